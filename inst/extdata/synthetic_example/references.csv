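"indicator_id","ecosystem_id","unit_id","ref_value","definition_tag","scaling_model"
"ind001","eco01","unit01","57.929554650547793","past_knowledge","minimal"
"ind001","eco01","unit02","63.210462392260204","past_knowledge","minimal"
"ind001","eco01","unit03","47.952326562737568","past_knowledge","minimal"
"ind001","eco01","unit04","67.255690340172606","past_knowledge","minimal"
"ind001","eco01","unit05","79.020939329709933","past_knowledge","minimal"
"ind001","eco01","unit06","84.976498198056078","past_knowledge","minimal"
"ind002","eco01","unit01","92.637146389107741","pristine","minimal"
"ind002","eco01","unit02","78.009298773197216","pristine","minimal"
"ind002","eco01","unit03","86.177717675961901","pristine","minimal"
"ind002","eco01","unit04","72.643631695704073","pristine","minimal"
"ind002","eco01","unit05","87.962157161422738","pristine","minimal"
"ind002","eco01","unit06","56.909730306967489","pristine","minimal"
"ind003","eco01","unit01","69.596277566644659","pristine","minimal"
"ind003","eco01","unit02","76.12568812494915","pristine","minimal"
"ind003","eco01","unit03","62.323054413967142","pristine","minimal"
"ind003","eco01","unit04","54.692219611271476","pristine","minimal"
"ind003","eco01","unit05","72.971459174907068","pristine","minimal"
"ind003","eco01","unit06","52.357830614940539","pristine","minimal"
"ind004","eco01","unit01","38.335974293759229","pristine","optimal"
"ind004","eco01","unit02","43.514139792553877","pristine","optimal"
"ind004","eco01","unit03","37.57518829419503","pristine","optimal"
"ind004","eco01","unit04","31.508459128619407","pristine","optimal"
"ind004","eco01","unit05","29.816829647552382","pristine","optimal"
"ind004","eco01","unit06","36.392641163968811","pristine","optimal"
"ind005","eco02","unit01","35.368807348136698","pristine","minimal"
"ind005","eco02","unit02","35.368807348136698","pristine","minimal"
"ind005","eco02","unit03","35.368807348136698","pristine","minimal"
"ind005","eco02","unit04","35.368807348136698","pristine","minimal"
"ind005","eco02","unit05","35.368807348136698","pristine","minimal"
"ind005","eco02","unit06","35.368807348136698","pristine","minimal"
"ind006","eco02","unit01","46.888172376913865","pristine","maximal"
"ind006","eco02","unit02","56.72061508969567","pristine","maximal"
"ind006","eco02","unit03","66.042608282983409","pristine","maximal"
"ind006","eco02","unit04","45.506138564429818","pristine","maximal"
"ind006","eco02","unit05","40.264827169051429","pristine","maximal"
"ind006","eco02","unit06","62.581238001866687","pristine","maximal"
"ind007","eco02","unit01","65.38718355528701","pristine","optimal"
"ind007","eco02","unit02","63.929461452157049","pristine","optimal"
"ind007","eco02","unit03","53.838247342187586","pristine","optimal"
"ind007","eco02","unit04","58.569104052277567","pristine","optimal"
"ind007","eco02","unit05","54.613780998978704","pristine","optimal"
"ind007","eco02","unit06","77.346339484844478","pristine","optimal"
"ind008","eco02","unit01","63.16722316426673","best_index","minimal"
"ind008","eco02","unit02","83.39979358767674","best_index","minimal"
"ind008","eco02","unit03","79.519717649571547","best_index","minimal"
"ind008","eco02","unit04","56.493215368140831","best_index","minimal"
"ind008","eco02","unit05","55.785223030963067","best_index","minimal"
"ind008","eco02","unit06","78.849791211434294","best_index","minimal"
"ind009","eco03","unit01","75.970731924629348","past_knowledge","optimal"
"ind009","eco03","unit02","51.219355204394418","past_knowledge","optimal"
"ind009","eco03","unit03","42.909180173302715","past_knowledge","optimal"
"ind009","eco03","unit04","63.811701526600913","past_knowledge","optimal"
"ind009","eco03","unit05","61.787897945070704","past_knowledge","optimal"
"ind009","eco03","unit06","57.007540714007988","past_knowledge","optimal"
"ind010","eco03","unit01","107.02032376502807","pristine","minimal"
"ind010","eco03","unit02","101.25885150637754","pristine","minimal"
"ind010","eco03","unit03","91.661260865145806","pristine","minimal"
"ind010","eco03","unit04","100.49995602608614","pristine","minimal"
"ind010","eco03","unit05","97.36663782865169","pristine","minimal"
"ind010","eco03","unit06","108.75419258215979","pristine","minimal"
"ind011","eco03","unit01","27.386999681920173","past_knowledge","minimal"
"ind011","eco03","unit02","35.624947437149984","past_knowledge","minimal"
"ind011","eco03","unit03","23.85415426257088","past_knowledge","minimal"
"ind011","eco03","unit04","23.061859352914713","past_knowledge","minimal"
"ind011","eco03","unit05","21.566570564174651","past_knowledge","minimal"
"ind011","eco03","unit06","28.718400107670099","past_knowledge","minimal"
"ind012","eco03","unit01","13.7298764016584","pristine","optimal"
"ind012","eco03","unit02","15.153472720118796","pristine","optimal"
"ind012","eco03","unit03","14.467855935749975","pristine","optimal"
"ind012","eco03","unit04","16.294030644630546","pristine","optimal"
"ind012","eco03","unit05","15.430942109880117","pristine","optimal"
"ind012","eco03","unit06","13.035413038923053","pristine","optimal"
"ind001","eco02","unit01","61.354977308742647","pristine","minimal"
"ind001","eco02","unit02","48.93558442541287","pristine","minimal"
"ind001","eco02","unit03","58.199024389848319","pristine","minimal"
"ind001","eco02","unit04","70.671951925551369","pristine","minimal"
"ind001","eco02","unit05","53.307476544029427","pristine","minimal"
"ind001","eco02","unit06","75.409774236871215","pristine","minimal"
"ind005","eco03","unit01","33.156789600009894","precautionary","minimal"
"ind005","eco03","unit02","21.845534933370619","precautionary","minimal"
"ind005","eco03","unit03","30.738838868609477","precautionary","minimal"
"ind005","eco03","unit04","51.862784311646998","precautionary","minimal"
"ind005","eco03","unit05","28.223304225332694","precautionary","minimal"
"ind005","eco03","unit06","29.950646588710665","precautionary","minimal"
"ind010","eco01","unit01","100.54023629407381","precautionary","minimal"
"ind010","eco01","unit02","83.944716220498464","precautionary","minimal"
"ind010","eco01","unit03","91.074867628669764","precautionary","minimal"
"ind010","eco01","unit04","135.12610705378225","precautionary","minimal"
"ind010","eco01","unit05","65.032296172983223","precautionary","minimal"
"ind010","eco01","unit06","97.710597274239177","precautionary","minimal"
"ind011","eco01","unit01","24.865880151445285","past_knowledge","minimal"
"ind011","eco01","unit02","28.403811542130878","past_knowledge","minimal"
"ind011","eco01","unit03","22.586565007646875","past_knowledge","minimal"
"ind011","eco01","unit04","27.700430303062259","past_knowledge","minimal"
"ind011","eco01","unit05","21.379832397353564","past_knowledge","minimal"
"ind011","eco01","unit06","26.414988827113135","past_knowledge","minimal"
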
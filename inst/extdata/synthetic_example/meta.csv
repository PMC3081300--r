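"indicator_id","ecosystem_id","membership","group_id","extra_representative"
"ind001","eco01","0.69999999999999996","primary_producer_generalist",FALSE
"ind002","eco01","1","intermediate_predator_generalist",FALSE
"ind003","eco01","1","top_predator_generalist",FALSE
"ind004","eco01","1","primary_producer_specialist",FALSE
"ind005","eco02","0.69999999999999996","top_predator_generalist",TRUE
"ind006","eco02","1","primary_consumer",FALSE
"ind007","eco02","1","top_predator_generalist",FALSE
"ind008","eco02","1","primary_producer_generalist",FALSE
"ind009","eco03","1","intermediate_predator_specialist",FALSE
"ind010","eco03","0.69999999999999996","primary_producer_specialist",FALSE
"ind011","eco03","0.69999999999999996","intermediate_predator_specialist",FALSE
"ind012","eco03","1","top_predator_specialist",FALSE
"ind001","eco02","0.29999999999999999","primary_producer_generalist",FALSE
"ind005","eco03","0.29999999999999999","top_predator_generalist",TRUE
"ind010","eco01","0.29999999999999999","primary_producer_specialist",FALSE
"ind011","eco01","0.29999999999999999","intermediate_predator_specialist",FALSE
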
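"unit_id","ecosystem_id","total_area","ecosystem_area"
"unit01","eco01","681.9705440480443","252.72296907956814"
"unit01","eco02","681.9705440480443","80.326755129383017"
"unit01","eco03","681.9705440480443","348.92081983909316"
"unit02","eco01","508.9902190111091","130.76040262532834"
"unit02","eco02","508.9902190111091","118.51172099957952"
"unit02","eco03","508.9902190111091","259.7180953862013"
"unit03","eco01","735.96704403035028","255.52922597777419"
"unit03","eco02","735.96704403035028","378.79585531243254"
"unit03","eco03","735.96704403035028","101.6419627401436"
"unit04","eco01","944.68604160499683","90.609976632938583"
"unit04","eco02","944.68604160499683","33.252711910301713"
"unit04","eco03","944.68604160499683","820.82335306175651"
"unit05","eco01","601.90270638547247","147.15916225017088"
"unit05","eco02","601.90270638547247","384.40264036964845"
"unit05","eco03","601.90270638547247","70.34090376565311"
"unit06","eco01","460.89992175139412","229.29802688772799"
"unit06","eco02","460.89992175139412","75.447133143291495"
"unit06","eco03","460.89992175139412","156.15476172037464"
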
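"scope","date","true_index"
"eco01",1950,0.8
"eco02",1950,0.8
"eco03",1950,0.8
"all",1950,0.8
"eco01",1990,0.733333333333333
"eco02",1990,0.733333333333333
"eco03",1990,0.733333333333333
"all",1990,0.733333333333333
"eco01",2000,0.666666666666667
"eco02",2000,0.666666666666667
"eco03",2000,0.666666666666667
"all",2000,0.666666666666667
"eco01",2010,0.6
"eco02",2010,0.6
"eco03",2010,0.6
"all",2010,0.6
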
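"id","count","rosettes"
"head",10,FALSE
"d1",14,FALSE
"d2",18,FALSE
"d3",22,FALSE
"d4",26,FALSE
"d5",30,FALSE
"d6",34,FALSE
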
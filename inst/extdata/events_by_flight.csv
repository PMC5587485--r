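proximity,flight,acoustics_n,no_acoustics_n
near,straight,153,114
near,curved,116,29
near,erratic,15,7
mid,straight,22,122
mid,curved,45,78
mid,erratic,9,33
far,straight,5,0
far,curved,11,11
far,erratic,7,7
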
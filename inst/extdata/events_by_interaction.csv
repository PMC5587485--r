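proximity,interaction,acoustics_n,no_acoustics_n
near,yes,0,0
near,no,0,6
mid,yes,1,2
mid,no,3,11
far,yes,1,1
far,no,1,1
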
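night,acoustic_n,visual_n,synchronous_n
09/08,19,24,12
09/09,24,43,13
09/10,324,20,13
09/11,291,7,4
09/12,79,3,2
09/15,36,19,3
09/16,229,47,21
09/17,330,27,9
09/18,2,56,0
09/19,7,24,1
09/22,7,13,1
09/23,3,17,1
09/24,3,22,0
09/25,1,20,0
10/06,30,15,5
10/07,74,16,3
10/08,496,243,232
10/09,347,107,49
10/13,157,32,10
10/14,76,29,4
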
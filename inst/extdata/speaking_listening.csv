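interval,1,2,3,4,5
Sep,3,39,161,195,72
Oct,13,34,169,171,61
Nov,6,36,197,168,66
Dec,9,52,206,158,44
Jan,9,60,168,168,50
Feb,13,53,183,142,36
Mar,11,52,195,140,40
Apr,12,49,186,140,31
May,17,59,209,121,30
Jun,22,60,213,115,25
Jul,22,71,171,105,33
Aug,13,64,211,79,24
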
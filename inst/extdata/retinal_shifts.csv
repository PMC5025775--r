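site,state,shift_ppm,reference
RET:C5,rhodopsin,131.0,TMS
RET:C5,Meta-II,126.0,TMS
RET:C18,rhodopsin,21.6,TMS
RET:C18,Meta-II,20.9,TMS
RET:C19,rhodopsin,14.7,TMS
RET:C19,Meta-II,13.8,TMS
RET:C20,rhodopsin,16.4,TMS
RET:C20,Meta-II,13.7,TMS
TYR268:CZ,rhodopsin,155.2,TMS
TYR268:CZ,Meta-II,156.1,TMS
TYR191:CZ,rhodopsin,156.6,TMS
TYR191:CZ,Meta-II,159.3,TMS
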
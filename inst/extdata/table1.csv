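residue1,residue2,component,polarity,association,intersubunit,excluded,exclusion_reason,printed_font
Q84,P205,first,neg,o,FALSE,FALSE,none,regular
A81,L207,first,neg,o,FALSE,FALSE,none,regular
S83,T289,single,neg,o,TRUE,FALSE,none,bold
S83,Q358,first,pos,o,TRUE,FALSE,none,bold
S83,E359,single,neg,o,TRUE,FALSE,none,italic
A81,L369,first,neg,less_than_o,TRUE,FALSE,none,bold
A81,Y417,single,neg,i,FALSE,FALSE,none,bold
S83,Y417,single,neg,i,FALSE,FALSE,none,bold
Q84,Y417,single,neg,i,FALSE,FALSE,none,regular
A81,P205,single,pos,i,FALSE,TRUE,distance_gt_20A,regular
S83,P205,single,neg,i,FALSE,FALSE,none,regular
Q84,R206,single,neg,d,FALSE,FALSE,none,regular
Q84,L207,single,neg,i,FALSE,FALSE,none,regular
A81,K208,single,neg,i,FALSE,FALSE,none,bold
A81,T209,single,neg,i,FALSE,TRUE,non_desensitizing,bold
A81,M210,single,pos,i,FALSE,FALSE,none,italic
A81,T289,single,neg,i,TRUE,FALSE,none,italic
Q84,T289,single,neg,i,TRUE,FALSE,none,bold
S83,D357,first,neg,d,TRUE,FALSE,none,bold
S83,Q358,second,neg,d,TRUE,FALSE,none,regular
A81,L369,second,pos,d,TRUE,FALSE,none,italic
S83,L369,second,pos,i,TRUE,FALSE,none,regular
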
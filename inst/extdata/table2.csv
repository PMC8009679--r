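residue1,residue2,avg_distance_A,delta_open_closed_A,delta_desens_open_A
A81,Y417,8.4,0.3,-1.5
S83,Y417,10.9,0.0,-2.7
Q84,Y417,10.5,0.0,-0.4
A81,P205,23.5,0.1,-0.5
S83,P205,17.4,-0.4,-0.4
Q84,P205,13.0,-0.1,-0.6
Q84,R206,11.0,-0.2,0.0
A81,L207,19.6,0.4,-2.1
Q84,L207,10.6,-0.2,0.7
A81,K208,15.0,0.3,-1.3
A81,T209,13.1,-0.2,-3.1
A81,M210,11.7,-0.4,-3.0
A81,T289,8.5,0.2,2.2
S83,T289,12.4,-2.0,-0.9
Q84,T289,16.2,-0.8,-1.7
S83,D357,11.5,3.6,-1.7
S83,Q358,7.1,4.5,-0.5
S83,E359,8.8,3.0,-1.0
A81,L369,10.9,-2.4,-2.1
S83,L369,18.2,-3.7,-0.9
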
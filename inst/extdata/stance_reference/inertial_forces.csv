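position,segment,fx,fy,fz,printed_N
1,leg_foot,17,13,-3,22
2,thigh,-12,-4,-7,15
2,leg_foot,-41,-10,9,43
3,thigh,-3,-11,-2,12
3,leg_foot,4,-3,-4,7
4,thigh,12,9,-7,16
4,leg_foot,16,-1,-7,18
5,thigh,-15,8,2,17
5,leg_foot,30,-8,2,32
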
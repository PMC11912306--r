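effect_id,parent_id,effect,time_point_start,time_point_end
1,,no embryo,0,120
2,,coagulated,0,120
3,,normal,0,120
4,,abnormal eye,0,120
5,,abnormal tail effects,0,120
6,,developmental delay effects,0,120
7,,deformation/malformation,0,120
8,,abnormal behavior,0,120
9,,heartbeat,48,120
10,,abnormal blood circulation,48,120
11,,edema,24,120
12,,abnormal pigmentation,48,120
13,,abnormal hatching,48,120
14,,abnormal swim bladder,72,120
15,,necrosis,0,120
16,,miscellaneous,0,120
17,4,no eye,0,120
18,4,abnormal eye size,0,120
19,5,abnormal tail,0,120
20,5,abnormal tail tip,0,120
21,5,abnormal tail fin,0,120
22,5,abnormal tail length,0,120
23,5,lack of somites,0,120
24,5,no tail detachment,0,120
25,6,developmental delay,0,120
26,6,hours post fertilization,0,120
27,7,deformation head,0,120
28,7,smaller head,0,120
29,7,deformation yolk sac,0,120
30,7,malformation sacculi/otoliths,0,120
31,7,modified structure of chorda,0,120
32,7,scoliosis,0,120
33,7,abnormal heart,48,120
34,8,shivering,0,120
35,8,tremor,0,120
36,8,no spontaneous tail contraction,0,30
37,8,no movement after hatching,72,120
38,9,decreased heartbeat,48,120
39,9,increased heartbeat,48,120
40,9,no heartbeat,48,120
41,9,beats per minute,48,120
42,10,no blood circulation,48,120
43,10,blood congestion,48,120
44,11,yolk sac edema,24,120
45,11,pericardium edema,24,120
46,12,no pigmentation,48,120
47,12,low pigmentation,48,120
48,12,increased pigmentation,48,120
49,13,early hatching,48,72
50,13,no hatching,72,120
51,14,no swim bladder,72,120
52,14,smaller swim bladder,72,120
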
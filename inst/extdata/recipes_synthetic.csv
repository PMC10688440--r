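ingredients,product,trajectory,tier,innovation_score,tier_score,rank
,a1,basic_a,0,6,0,0
,a2,basic_a,0,8,0,0
,a3,basic_a,0,10,0,0
,b1,basic_b,0,6,0,0
,b2,basic_b,0,8,0,0
,b3,basic_b,0,10,0,0
a1;a2;a3,1a,a,1,48,48,1
1a;a1;a2,2a,a,2,109,109,2
2a;a1;a2,3a,a,3,188,188,3
b1;b2;b3,1b,b,1,48,48,1
1b;b1;b2,2b,b,2,109,109,2
2b;b1;b2,3b,b,3,188,188,3
3a;3b;a3,x4,crossover,4,358,358,4
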
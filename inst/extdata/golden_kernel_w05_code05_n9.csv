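index,W
1,1.573015021737620
2,1.724186530902597
3,1.892551680050757
4,2.051547254763982
5,2.079262087636907
6,2.188870453332122
7,2.327713070448559
8,2.455031732311024
9,2.554530043156235
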
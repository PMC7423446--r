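"order","child_order_1","child_order_2","mean_radius_mm","mean_length_mm"
1,NA,NA,1.125,6.75
2,1,0,1.41741118113173,8.50446708679039
3,2,1,1.78582618346422,10.7149571007853
4,3,2,2.25,13.5
5,4,3,2.83482236226346,17.0089341735808
6,5,4,3.57165236692845,21.4299142015707
7,6,5,4.5,27
8,7,6,5.66964472452693,34.0178683471616
9,8,7,7.1433047338569,42.8598284031414
10,9,8,9,54
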
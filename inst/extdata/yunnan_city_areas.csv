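city,unsuitable_km2,subsuitable_km2,suitable_km2
Baoshan,5225.1,12218.8,1750.5
Chuxiong,21580.1,6085.2,827.2
Dali,20562.4,7422.9,458.7
Dehong,251.1,8043.3,2952.7
Diqing,23152.4,123.1,0
Honghe,7240.7,18165.3,6687.6
Kunming,18320.4,2278.2,403.8
Lijiang,18446.0,1752.1,416.9
Lincang,6939.5,14713.6,2099.2
Nujiang,12369.8,1899.0,370.1
Puer,5133.2,25539.7,13715.7
Qujing,24781.4,3917.8,143.6
Wenshan,7646.1,22363.0,1276.9
Xishuangbanna,1944.1,7751.1,9331.7
Yuxi,7007.6,6272.3,1675.8
Zhaotong,22110.2,187.1,14.0
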
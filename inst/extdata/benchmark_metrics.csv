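dataset,classifier,acc,prec,rec,spe,f1,auc
D1,V7,0.7928,0.6875,0.9361,0.6875,0.7928,0.9069
D1,V16,0.8288,0.9667,0.6170,0.9843,0.7532,0.8562
D1,V19,0.8829,0.8542,0.8723,0.8906,0.8632,0.8820
D1,V21,0.9190,0.9750,0.8298,0.9844,0.8966,0.8688
D1,V24,0.7387,0.6731,0.7447,0.7343,0.7070,0.7931
D1,R34,0.8198,0.8462,0.7021,0.9063,0.7674,0.9034
D1,D121,0.8018,0.8209,0.6809,0.8906,0.7442,0.8443
D2,V7,0.8508,0.9020,0.7817,0.9176,0.8376,0.8860
D2,V16,0.8605,0.8799,0.8300,0.8901,0.8542,0.9255
D2,V19,0.8410,0.8329,0.8470,0.8352,0.8399,0.9176
D2,V21,0.8800,0.9495,0.7989,0.9588,0.8677,0.9181
D2,V24,0.8397,0.9075,0.7507,0.9258,0.8217,0.8768
D2,R34,0.8787,0.9030,0.8442,0.9121,0.8726,0.9324
D2,D121,0.9317,0.9634,0.8952,0.9670,0.9280,0.9745
D3,V7,0.8059,0.9240,0.7932,0.9366,0.8536,0.9267
D3,V16,0.9679,0.9824,0.9518,0.9835,0.9669,0.9909
D3,V19,0.9791,0.9829,0.9745,0.9835,0.9787,0.9920
D3,V21,0.9807,0.9775,0.9830,0.9780,0.9802,0.9933
D3,V24,0.9553,0.9848,0.2350,0.9862,0.5320,0.9713
D3,R34,0.8842,0.9856,0.7762,0.9890,0.8685,0.9186
D3,D121,0.7824,0.9900,0.5637,0.9945,0.7184,0.8677
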
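candidate_id,pred_pim1,h_pim1,pred_pim2,h_pim2
68328588,7.782,0.122,7.455,0.213
45377352,10.367,0.906,9.497,1.117
68328129,7.316,0.352,7.243,0.162
68327929,8.332,0.102,7.513,0.330
68328158,8.311,0.074,7.072,1.109
68328259,8.434,0.113,7.958,0.106
68328426,8.347,0.089,8.026,0.151
68328539,8.137,0.387,6.699,0.111
68328547,8.282,0.1023,7.594,0.0964
68328676,8.138,0.0739,7.068,0.7669
68328891,8.329,0.0860,8.244,0.2909
68356801,8.745,0.2543,8.137,0.9468
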
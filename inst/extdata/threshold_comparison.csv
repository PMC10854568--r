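fold,threshold,set,sensitivity,precision,f1
1,None,Val,0.961,0.452,0.615
1,0.96,Val,0.811,0.854,0.832
1,None,Test,0.954,0.239,0.383
1,0.96,Test,0.776,0.756,0.766
2,None,Val,0.919,0.557,0.694
2,0.84,Val,0.778,0.857,0.815
2,None,Test,0.959,0.281,0.435
2,0.84,Test,0.827,0.633,0.717
3,None,Val,0.935,0.398,0.558
3,0.91,Val,0.819,0.840,0.830
3,None,Test,0.944,0.244,0.387
3,0.91,Test,0.806,0.731,0.767
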
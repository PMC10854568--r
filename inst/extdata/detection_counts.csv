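table,magnification,fold,data,set,sensitivity,precision,f1,tp,fp,fn
initial_magnification,40x,1,Initial,Val,0.967,0.720,0.826,590,229,20
initial_magnification,40x,1,Initial,Test,0.957,0.132,0.232,135,890,6
initial_magnification,40x,2,Initial,Val,0.922,0.786,0.849,847,230,72
initial_magnification,40x,2,Initial,Test,0.965,0.173,0.294,136,649,5
initial_magnification,40x,3,Initial,Val,0.944,0.724,0.819,503,192,30
initial_magnification,40x,3,Initial,Test,0.957,0.185,0.311,135,593,6
initial_magnification,20x,1,Initial,Val,0.957,0.484,0.643,582,620,26
initial_magnification,20x,1,Initial,Test,0.932,0.207,0.338,137,526,10
initial_magnification,20x,2,Initial,Val,0.895,0.567,0.694,810,619,95
initial_magnification,20x,2,Initial,Test,0.918,0.221,0.356,135,477,12
initial_magnification,20x,3,Initial,Val,0.897,0.545,0.678,477,399,55
initial_magnification,20x,3,Initial,Test,0.905,0.320,0.473,133,282,14
initial_vs_updated,20x,1,Initial,Val,0.957,0.484,0.643,582,620,26
initial_vs_updated,20x,1,Updated,Val,0.961,0.452,0.615,610,740,25
initial_vs_updated,20x,1,Initial,Test,0.932,0.207,0.338,137,526,10
initial_vs_updated,20x,1,Updated,Test,0.954,0.239,0.383,187,594,9
initial_vs_updated,20x,2,Initial,Val,0.895,0.567,0.694,810,619,95
initial_vs_updated,20x,2,Updated,Val,0.919,0.557,0.694,877,698,77
initial_vs_updated,20x,2,Initial,Test,0.918,0.221,0.356,135,477,12
initial_vs_updated,20x,2,Updated,Test,0.959,0.281,0.435,188,480,8
initial_vs_updated,20x,3,Initial,Val,0.897,0.545,0.678,477,399,55
initial_vs_updated,20x,3,Updated,Val,0.935,0.398,0.558,528,798,37
initial_vs_updated,20x,3,Initial,Test,0.905,0.320,0.473,133,282,14
initial_vs_updated,20x,3,Updated,Test,0.944,0.244,0.387,185,574,11
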
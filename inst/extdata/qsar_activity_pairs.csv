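model,molecule,split,observed,predicted,rel_err_printed
neurotoxicity,1MNAP,test,-43.422,-47.198,-8.70
neurotoxicity,2MNAP,test,-46.392,-47.670,-2.75
neurotoxicity,ACE,training,-32.347,-32.025,1.00
neurotoxicity,ANY,training,-43.915,-44.111,-0.45
neurotoxicity,BaAN,training,-55.501,-55.371,0.23
neurotoxicity,BANN,training,-60.793,-60.801,-0.01
neurotoxicity,BaP,training,-70.481,-70.748,-0.38
neurotoxicity,BbF,training,-44.365,-44.287,0.18
neurotoxicity,BeP,training,-67.026,-67.011,0.02
neurotoxicity,BghiP,training,-64.460,-64.604,-0.22
neurotoxicity,BkF,training,-50.842,-50.926,-0.17
neurotoxicity,CHR,training,-66.290,-65.886,0.61
neurotoxicity,CRN,training,-83.141,-83.186,-0.05
neurotoxicity,DahA,test,-66.480,-56.925,14.37
neurotoxicity,FLR,test,-41.383,-46.911,-13.36
neurotoxicity,FRT,training,-49.042,-48.781,0.53
neurotoxicity,IcdP,training,-65.071,-65.138,-0.10
neurotoxicity,NAP,training,-26.336,-26.624,-1.09
neurotoxicity,PHE,training,-34.993,-35.103,-0.31
neurotoxicity,PYR,test,-48.667,-53.742,-10.43
immunotoxicity,1MNAP,test,-61.808,-41.487,32.88
immunotoxicity,2MNAP,training,-47.673,-47.812,-0.29
immunotoxicity,ACE,training,-68.893,-68.577,0.46
immunotoxicity,ACY,training,-53.244,-53.560,-0.59
immunotoxicity,ANT,training,-69.617,-69.599,0.03
immunotoxicity,BaAN,training,-91.938,-91.803,0.15
immunotoxicity,BaP,training,-97.864,-97.145,0.73
immunotoxicity,BbF,training,-103.742,-103.692,0.05
immunotoxicity,BghiP,training,-121.288,-121.378,-0.07
immunotoxicity,BkF,training,-112.373,-112.617,-0.22
immunotoxicity,CHR,training,-83.232,-83.945,-0.86
immunotoxicity,CPPHN,test,-78.146,-66.951,14.33
immunotoxicity,CRN,test,-113.449,-86.764,23.52
immunotoxicity,DahA,training,-105.255,-105.328,-0.07
immunotoxicity,FLR,training,-67.423,-67.182,0.36
immunotoxicity,FRT,test,-104.230,-75.363,27.70
immunotoxicity,NAP,training,-33.803,-33.696,0.32
immunotoxicity,PHE,training,-54.440,-54.451,-0.02
immunotoxicity,PYR,test,-92.176,-75.580,18.00
phytotoxicity,1MNAP,training,-37.273,-37.162,0.30
phytotoxicity,2MNAP,training,-42.014,-42.319,-0.73
phytotoxicity,ACE,training,-54.961,-54.710,0.46
phytotoxicity,ACY,training,-53.263,-53.552,-0.54
phytotoxicity,ANT,training,-64.852,-64.844,0.01
phytotoxicity,BANN,test,-97.418,-109.937,-12.85
phytotoxicity,BaP,training,-103.536,-103.504,0.03
phytotoxicity,BbF,training,-100.331,-100.260,0.07
phytotoxicity,BeP,training,-74.155,-73.930,0.30
phytotoxicity,BghiP,training,-98.467,-98.653,-0.19
phytotoxicity,BkF,test,-81.132,-60.361,25.60
phytotoxicity,CPPHN,test,-81.077,-45.480,43.91
phytotoxicity,CRN,training,-86.995,-86.975,0.02
phytotoxicity,DahA,test,-81.625,-62.226,23.77
phytotoxicity,FLR,test,-83.469,-56.276,32.58
phytotoxicity,FRT,training,-76.780,-76.825,-0.06
phytotoxicity,NAP,training,-51.637,-51.298,0.66
phytotoxicity,PHE,training,-64.850,-65.097,-0.38
phytotoxicity,PRL,training,-93.434,-93.337,0.10
phytotoxicity,PYR,training,-89.548,-89.631,-0.09
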
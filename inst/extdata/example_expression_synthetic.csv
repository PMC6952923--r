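mirna_id,disease,fc,log2fc
mir-sim-0012,AD,6.85972264562913,2.77815024609713
mir-sim-0003,AD,2.19038597141667,1.13118511182879
mir-sim-0005,AD,0.323655571615264,-1.62746875531933
mir-sim-0002,AD,0.519674352534227,-0.944320235390367
mir-sim-0007,AD,0.192651297873703,-2.37593618955615
mir-sim-0009,AD,0.458603226911533,-1.12468158856681
mir-sim-0006,AD,0.231388721759111,-2.11160954789543
mir-sim-0011,AD,0.580642230201693,-0.784278591667273
mir-sim-0008,COPD,3.45209274166625,1.78747122353909
mir-sim-0001,COPD,1.26869575324086,0.343346137014255
mir-sim-0004,COPD,1.31126976712187,0.390964521297289
mir-sim-0006,COPD,0.281462246555009,-1.82898667297475
mir-sim-0011,COPD,3.45919936091824,1.79043816164954
mir-sim-0009,COPD,4.60493010492904,2.20317925880575
mir-sim-0007,COPD,0.271750940805323,-1.87964306499697
mir-sim-0010,COPD,1.35046879533819,0.43346030454073
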
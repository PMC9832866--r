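{"species":{"spA":{"genes":37,"expressed_degs":25,"seed":"spA_TF_L1_01","nodes":24,"edges":113,"levels":4,"hubs":0},"spB":{"genes":37,"expressed_degs":25,"seed":"spB_TF_L1_01","nodes":24,"edges":117,"levels":4,"hubs":0}},"consensus":{"nodes":20,"edges":66},"specific":[47,51],"thresholds":{"cutoff":0.81,"lfcCutoff":1,"fdrCutoff":0.05,"minMeanTPM":0.5,"hubCutoff":6,"pCutoff":0.0001,"upstreamLength":500,"sampleMode":"means","stageRule":"profile"}}
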
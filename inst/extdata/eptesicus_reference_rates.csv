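trait_set,engine,rate_isabellinus,rate_serotinus,rate_isabellinus_no_hybrids,rate_serotinus_no_hybrids,rate_global,rate_global_no_hybrids,hybrid_contribution
morphometry,DFA,84.5,78.3,96.0,66.7,81.7,84.0,13.6
morphometry,SVM,78.9,72.3,83.9,66.7,75.0,76.9,7.6
colour,DFA,92.3,37.5,92.3,47.1,71.4,78.6,25.2
colour,SVM,92.3,29.2,77.1,75.0,68.3,76.8,26.8
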
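{"dose_grid":[30,90,150],"skeletons":[[0.05,0.1,0.2],[0.08,0.2,0.4]],"prior_model_probs":[0.5,0.5],"alpha_prior_sd":0.707106781186547,"target_toxicity":0.2,"overdose_threshold":0.85,"cohort_size":3,"max_patients":18,"estimator":"plugin","quadrature":{"bound_sd":8,"nodes":4097,"rel_tol":1e-08}}
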
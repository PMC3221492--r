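# Reference validation results for the meloxicam powder-blend NIR assay:
# per-level mean predicted concentration and beta-expectation tolerance
# limits (relative, %) with the corresponding relative acceptance limits.
nominal,mean_pred,rel_tol_lower,rel_tol_upper,acceptance_lower,acceptance_upper
10.00,10.03,-3.022,3.557,-5,5
12.50,12.60,-1.943,3.539,-5,5
15.00,15.03,-2.564,3.028,-5,5
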
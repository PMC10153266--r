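# Boundary-ratio response coefficients, regenerated deterministically by
# generate_boundary_coefs(): bounded least-squares fit of the magnitude
# responses to the exact forward-model ratios pooled over rho in [0.5, 1]
# on a log gamma grid [1e-2, 1e2] (step 0.05 decades).
limit,d_mu,c1,c2,c3,c4
zero,0,0.267142121898421,0.717140436084169,0,1.55665248858468
zero,1,1.18097756749936,0.913189741571817,0.0742419324292007,0.0934170089561366
inf,0,1.1378130011176,0.281908024302167,0.835905334701502,0
inf,1,0,0,4.83187975736674,0.868053861242998
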
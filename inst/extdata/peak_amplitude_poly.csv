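# Degree-10 zero-intercept polynomial coefficients for the theoretical
# minimum of dK2/dln(T) vs rho (beta = 1), regenerated deterministically
# by generate_peak_poly(); generation grid rho = 0..1 step 0.005.
d_mu,degree,coef
0,1,-0.557409890678263
0,2,0.321566963827065
0,3,-0.0180529588518929
0,4,0.00113989378679905
0,5,-0.0612871934864838
0,6,0.107500460421732
0,7,-0.137953746102301
0,8,0.0700970320616419
0,9,0.00559821242100291
0,10,-0.0099019625175138
1,1,-0.332201657325195
1,2,0.201459068794191
1,3,-0.0170128613751561
1,4,-0.00251883679040091
1,5,-0.0527594329199804
1,6,0.121958214557229
1,7,-0.21673520651324
1,8,0.22198359314327
1,9,-0.112743213533638
1,10,0.022470351410873
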
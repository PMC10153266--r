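# Irregular "typical" multi-exposure ladder: 15 exposures, 50 us - 80 ms,
# following the exposure lists commonly used in multi-exposure speckle
# imaging practice. Editable; values in seconds, strictly increasing.
exposure_s
5.0e-05
7.5e-05
1.0e-04
2.5e-04
5.0e-04
7.5e-04
1.0e-03
2.5e-03
5.0e-03
7.5e-03
1.0e-02
2.5e-02
5.0e-02
7.5e-02
8.0e-02
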
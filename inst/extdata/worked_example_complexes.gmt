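LSM_1-7_complex	mRNA decapping / degradation complex	LSM1	LSM2	LSM3	LSM4	LSM5	LSM6	LSM7
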
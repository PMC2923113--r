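module_id	method	class_label	k_param	rank_score	members
Lit-9	CPM	LIT	4	8	LSM1;LSM2;LSM3;LSM4;LSM5;LSM6;LSM7;SMN1
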
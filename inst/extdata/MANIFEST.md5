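902786724cbc462f74f297c88a0ab9f6  ataxin3_af_novel.tsv
c0db215da77fed32679f2d1eac466ce9  ataxin3_af_reported.tsv
5c6f504fe162943212474b6895961dd3  ataxin3_differential.tsv
548d1e1b3765791bd8261b642f14141a  ataxin3_dit_novel.tsv
e26dccee64f661d49f50f9470d39dad4  ataxin3_dit_reported.tsv
305245be329ce87e385b65f93ac9e2c6  ataxin3_no_solution.tsv
f1bb74c9b35027f52eeb3817f9219fe3  ir_synthetic.tsv
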
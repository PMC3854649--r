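globo	Glycosphingolipid biosynthesis - globo series	2523	2524	2717	3073	3074	4668	6482	6483	6489	8706	10317	10690	26301	53947
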
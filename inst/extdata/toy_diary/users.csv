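user_id,sex,age,prior_diagnosis,first_use_date
u1,female,30,migraine,2020-01-01
u2,male,,none,2020-01-01
u3,,45,,2020-01-01
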
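user_id,drug_name,dose,intake_time,migraine_specific
u1,Sumatriptan,50 mg,2020-01-02 09:30:00,
u1,Ibuprofen,400 mg,2020-01-10 23:00:00,
u1,Ibuprofen,400 mg,2020-02-05 10:30:00,
u2,Paracetamol,500 mg,2020-01-15 10:00:00,
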
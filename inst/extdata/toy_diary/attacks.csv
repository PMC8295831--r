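attack_id,user_id,start,end,max_intensity,unilateral,throbbing,worse_with_activity,nausea,vomitus,photophobia,phonophobia,aura
a1,u1,2020-01-02 09:00:00,2020-01-02 17:00:00,7,true,true,false,true,false,false,false,false
a2,u1,2020-01-10 22:00:00,2020-01-11 02:00:00,5,false,false,false,false,false,true,false,false
a3,u1,2020-01-20 08:00:00,2020-01-20 10:00:00,8,true,true,true,true,false,false,false,false
a4,u1,2020-02-05 10:00:00,2020-02-05 15:00:00,6,true,false,true,false,false,true,true,false
a5,u1,2020-02-20 09:00:00,2020-02-20 15:00:00,6,true,true,false,true,false,false,false,false
a6,u1,2020-03-10 09:00:00,2020-03-10 15:00:00,7,true,true,false,true,false,false,false,false
b1,u2,2020-01-03 10:00:00,2020-01-03 16:00:00,4,false,false,false,false,false,false,false,false
b2,u2,2020-01-15 09:00:00,2020-01-15 14:00:00,5,true,true,false,false,false,false,false,false
b3,u2,2020-02-10 07:00:00,2020-02-10 09:00:00,3,false,false,false,false,false,false,false,true
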
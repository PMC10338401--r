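category,subcategory,count
suturing,Suture puncture,412
suturing,Suture handling,570
suturing,"Suture, single",13
suturing,"Suture, running",37
dissection,"Dissection, ordinary",769
dissection,"Dissection, clips",125
dissection,Dissection hemostasis,82
other,Suction,46
other,Camera handling,1754
other,Changing instrument,34
other,Cleaning,7
other,Holding with 4. Arm,242
other,Holding with other instruments,2
other,External instrument (non-robot),310
other,Catheter placement,4
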
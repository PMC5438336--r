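compound_id,pic50,role
C01,7.110234,train
C02,4.823905,test
C03,7.156312,train
C04,5.537219,train
C05,11.80399,train
C06,6.996914,train
C07,10.49315,train
C08,10.13774,test
C09,3.484905,train
C10,3.960448,train
C11,8.150233,train
C12,3.688057,train
C13,1.852594,train
C14,7.918944,train
C15,6.805185,train
C16,9.203652,train
C17,8.758832,train
C18,9.409227,train
C19,12.51036,test
C20,4.20617,test
C21,4.341742,train
C22,4.969622,train
C23,7.255019,test
C24,5.751007,test
C25,2.486229,train
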
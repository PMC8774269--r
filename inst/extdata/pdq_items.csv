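item_id,task,smaller_amount,larger_amount,delay_days,win_probability,group
pdq01,probability,20,80,NA,0.026,block1
pdq02,probability,20,80,NA,0.042,block1
pdq03,probability,20,80,NA,0.068,block1
pdq04,probability,20,80,NA,0.1,block1
pdq05,probability,20,80,NA,0.143,block1
pdq06,probability,20,80,NA,0.211,block1
pdq07,probability,20,80,NA,0.302,block1
pdq08,probability,20,80,NA,0.423,block1
pdq09,probability,20,80,NA,0.545,block1
pdq10,probability,20,80,NA,0.667,block1
pdq11,probability,40,100,NA,0.051,block2
pdq12,probability,40,100,NA,0.081,block2
pdq13,probability,40,100,NA,0.128,block2
pdq14,probability,40,100,NA,0.182,block2
pdq15,probability,40,100,NA,0.25,block2
pdq16,probability,40,100,NA,0.348,block2
pdq17,probability,40,100,NA,0.464,block2
pdq18,probability,40,100,NA,0.595,block2
pdq19,probability,40,100,NA,0.706,block2
pdq20,probability,40,100,NA,0.8,block2
pdq21,probability,40,60,NA,0.138,block3
pdq22,probability,40,60,NA,0.21,block3
pdq23,probability,40,60,NA,0.306,block3
pdq24,probability,40,60,NA,0.4,block3
pdq25,probability,40,60,NA,0.5,block3
pdq26,probability,40,60,NA,0.615,block3
pdq27,probability,40,60,NA,0.722,block3
pdq28,probability,40,60,NA,0.815,block3
pdq29,probability,40,60,NA,0.878,block3
pdq30,probability,40,60,NA,0.923,block3
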
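item_id,task,smaller_amount,larger_amount,delay_days,win_probability,group
mcq01,delay,54,55,117,NA,medium
mcq02,delay,55,75,61,NA,large
mcq03,delay,19,25,53,NA,small
mcq04,delay,31,85,7,NA,large
mcq05,delay,14,25,19,NA,small
mcq06,delay,47,50,160,NA,medium
mcq07,delay,15,35,13,NA,small
mcq08,delay,25,60,14,NA,medium
mcq09,delay,78,80,162,NA,large
mcq10,delay,40,55,62,NA,medium
mcq11,delay,11,30,7,NA,small
mcq12,delay,67,75,119,NA,large
mcq13,delay,34,35,186,NA,small
mcq14,delay,27,50,21,NA,medium
mcq15,delay,69,85,91,NA,large
mcq16,delay,49,60,89,NA,medium
mcq17,delay,80,85,157,NA,large
mcq18,delay,24,35,29,NA,small
mcq19,delay,33,80,14,NA,large
mcq20,delay,28,30,179,NA,small
mcq21,delay,34,50,30,NA,medium
mcq22,delay,25,30,80,NA,small
mcq23,delay,41,75,20,NA,large
mcq24,delay,54,60,111,NA,medium
mcq25,delay,54,80,30,NA,large
mcq26,delay,22,25,136,NA,small
mcq27,delay,20,55,7,NA,medium
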
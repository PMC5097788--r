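gender,age,ejecfrac,theta_hat,se
F,<=65,high,-0.79100514599873006,0.25
F,<=65,medium,0.01842183395305047,0.25
F,<=65,low,-0.52945295527239566,0.25
F,>65,high,-0.65986711313138879,0.25
F,>65,medium,-0.40230863031735109,0.25
F,>65,low,-0.26933114113754913,0.25
M,<=65,high,-0.3022335616224569,0.12
M,<=65,medium,-0.4608476651932768,0.12
M,<=65,low,-0.29445580712926611,0.12
M,>65,high,0.026467135273923248,0.12
M,>65,medium,-0.33410642226143172,0.12
M,>65,low,-0.59507156894291535,0.12
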
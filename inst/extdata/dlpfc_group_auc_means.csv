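band,condition,power,mean_uvms,sd_uvms
theta,tms,low,18.7,10.3
theta,tms,high,22.5,14.4
alpha,tms,low,19.1,10.7
alpha,tms,high,22.0,13.9
beta,tms,low,18.5,9.9
beta,tms,high,22.7,14.6
theta,control,low,9.7,4.8
theta,control,high,11.2,6.3
alpha,control,low,9.7,4.8
alpha,control,high,11.3,6.3
beta,control,low,9.5,4.7
beta,control,high,11.4,6.4
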
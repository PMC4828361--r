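skill,measure,item,component,mean,sd,n
instep_kick,rom,hip,fe,129,11,22
instep_kick,rom,hip,aa,26,5,22
instep_kick,rom,hip,rot,17,4,22
instep_kick,rom,knee,fe,113,10,22
instep_kick,rom,knee,aa,23,6,22
instep_kick,rom,knee,rot,19,7,22
instep_kick,max_lengthening,rectus_femoris,,112.8,8.4,22
instep_kick,max_lengthening,vastus_lateralis,,104.2,6.1,22
instep_kick,max_lengthening,biceps_femoris,,119.3,6.6,22
instep_kick,max_lengthening,adductor_magnus,,174.6,11.6,22
instep_kick,max_lengthening,gracilis,,135.1,8.6,22
instep_kick,max_lengthening,gluteus_medius,,113.2,6.9,22
instep_kick,max_lengthening,semimembranosus,,127.7,8.6,22
fan_kick,rom,hip,fe,146.3,6.6,7
fan_kick,rom,hip,aa,87.8,5.6,7
fan_kick,rom,hip,rot,54.1,4.1,7
fan_kick,rom,knee,fe,108.9,6.3,7
fan_kick,rom,knee,aa,27.4,4.6,7
fan_kick,rom,knee,rot,28.2,4.1,7
fan_kick,max_lengthening,rectus_femoris,,104.2,4.1,7
fan_kick,max_lengthening,vastus_lateralis,,109.5,4.5,7
fan_kick,max_lengthening,biceps_femoris,,127.3,5.2,7
fan_kick,max_lengthening,adductor_magnus,,197.7,5.3,7
fan_kick,max_lengthening,gracilis,,134.7,4.8,7
fan_kick,max_lengthening,gluteus_medius,,127.9,4.0,7
fan_kick,max_lengthening,semimembranosus,,129.2,4.4,7
fan_kick,lengthening_speed,rectus_femoris,,0.26,0.02,7
fan_kick,lengthening_speed,vastus_lateralis,,0.09,0.00,7
fan_kick,lengthening_speed,biceps_femoris,,0.44,0.03,7
fan_kick,lengthening_speed,adductor_magnus,,0.42,0.04,7
fan_kick,lengthening_speed,gracilis,,0.13,0.00,7
fan_kick,lengthening_speed,gluteus_medius,,0.27,0.02,7
fan_kick,lengthening_speed,semimembranosus,,0.50,0.03,7
axe_kick,rom,hip,fe,162.2,8.4,13
axe_kick,rom,hip,aa,51.6,6.1,13
axe_kick,rom,hip,rot,57.9,5.3,13
axe_kick,rom,knee,fe,65.3,4.7,13
axe_kick,rom,knee,aa,28.8,4.1,13
axe_kick,rom,knee,rot,21.5,4.3,13
axe_kick,max_lengthening,rectus_femoris,,105.9,5.0,13
axe_kick,max_lengthening,vastus_lateralis,,103.6,3.9,13
axe_kick,max_lengthening,biceps_femoris,,132.0,4.7,13
axe_kick,max_lengthening,adductor_magnus,,171.3,4.9,13
axe_kick,max_lengthening,gracilis,,133.8,3.6,13
axe_kick,max_lengthening,gluteus_medius,,116.3,3.7,13
axe_kick,max_lengthening,semimembranosus,,133.8,4.3,13
axe_kick,lengthening_speed,rectus_femoris,,0.48,0.05,13
axe_kick,lengthening_speed,vastus_lateralis,,0.21,0.01,13
axe_kick,lengthening_speed,biceps_femoris,,0.69,0.05,13
axe_kick,lengthening_speed,adductor_magnus,,0.61,0.04,13
axe_kick,lengthening_speed,gracilis,,0.46,0.05,13
axe_kick,lengthening_speed,gluteus_medius,,0.29,0.02,13
axe_kick,lengthening_speed,semimembranosus,,0.71,0.06,13
pitch,max_lengthening,pectoralis_major,,129.3,6.2,9
pitch,max_lengthening,latissimus_dorsi,,130.5,7.1,9
pitch,peak_deceleration,shoulder,rot,6216,218,9
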
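T_K,property,value,units
300,rho_l,996.5,kg/m^3
320,rho_l,989.4,kg/m^3
340,rho_l,979.5,kg/m^3
360,rho_l,967.4,kg/m^3
380,rho_l,953.3,kg/m^3
400,rho_l,937.5,kg/m^3
420,rho_l,919.9,kg/m^3
440,rho_l,900.6,kg/m^3
460,rho_l,879.5,kg/m^3
480,rho_l,856.5,kg/m^3
500,rho_l,831.3,kg/m^3
520,rho_l,803.6,kg/m^3
540,rho_l,772.8,kg/m^3
560,rho_l,738,kg/m^3
580,rho_l,697.6,kg/m^3
600,rho_l,649.4,kg/m^3
620,rho_l,586.9,kg/m^3
640,rho_l,481.5,kg/m^3
300,rho_v,0.0256,kg/m^3
320,rho_v,0.0715,kg/m^3
340,rho_v,0.174,kg/m^3
360,rho_v,0.378,kg/m^3
380,rho_v,0.748,kg/m^3
400,rho_v,1.369,kg/m^3
420,rho_v,2.352,kg/m^3
440,rho_v,3.833,kg/m^3
460,rho_v,5.983,kg/m^3
480,rho_v,9.014,kg/m^3
500,rho_v,13.2,kg/m^3
520,rho_v,18.9,kg/m^3
540,rho_v,26.63,kg/m^3
560,rho_v,37.15,kg/m^3
580,rho_v,51.74,kg/m^3
600,rho_v,72.84,kg/m^3
620,rho_v,106.3,kg/m^3
640,rho_v,177.1,kg/m^3
300,p_v,0.003537,MPa
320,p_v,0.010546,MPa
340,p_v,0.027188,MPa
360,p_v,0.062194,MPa
380,p_v,0.12885,MPa
400,p_v,0.24577,MPa
420,p_v,0.4373,MPa
440,p_v,0.73367,MPa
460,p_v,1.1709,MPa
480,p_v,1.7905,MPa
500,p_v,2.639,MPa
520,p_v,3.769,MPa
540,p_v,5.237,MPa
560,p_v,7.106,MPa
580,p_v,9.448,MPa
600,p_v,12.345,MPa
620,p_v,15.901,MPa
640,p_v,20.265,MPa
300,gamma,71.686,mN/m
320,gamma,68.47,mN/m
340,gamma,65.04,mN/m
360,gamma,61.406,mN/m
380,gamma,57.581,mN/m
400,gamma,53.578,mN/m
420,gamma,49.411,mN/m
440,gamma,45.098,mN/m
460,gamma,40.655,mN/m
480,gamma,36.105,mN/m
500,gamma,31.472,mN/m
520,gamma,26.784,mN/m
540,gamma,22.077,mN/m
560,gamma,17.396,mN/m
580,gamma,12.8,mN/m
600,gamma,8.376,mN/m
620,gamma,4.268,mN/m
640,gamma,0.809,mN/m
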
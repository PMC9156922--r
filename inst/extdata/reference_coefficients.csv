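response,term,estimate,ci_lo,ci_hi,se,t,p
lc_al,intercept,0.53,0.49,0.57,0.022,24.36,9.99e-15
lc_al,model [Sprinter],0.010,-0.015,0.036,0.013,0.79,0.43
lc_al,model [Xtend],-0.037,-0.062,-0.011,0.013,-2.78,0.0056
lc_al,stiffness cat [Rec],-0.034,-0.059,-0.0088,0.013,-2.63,0.0088
lc_al,stiffness cat [+1],-0.064,-0.090,-0.038,0.013,-4.85,1.55e-6
lc_al,height [cm],0.0040,-0.0047,0.013,0.0045,0.89,0.37
lc_al,speed [m s^-1],0.066,0.062,0.070,0.0022,29.43,2e-16
lc_al,model [Sprinter]*speed [m s^-1],0.00036,-0.0046,0.0053,0.0025,0.14,0.89
lc_al,model [Xtend]*speed [m s^-1],0.0016,-0.0034,0.0066,0.0026,0.62,0.54
lc_al,stiffness cat [Rec]*speed [m s^-1],0.0022,-0.0027,0.0071,0.0025,0.88,0.38
lc_al,stiffness cat [+1]*speed [m s^-1],0.0039,-0.0011,0.0090,0.0026,1.53,0.13
lc_al,height [cm]*speed [m s^-1],0.00035,-0.0014,0.0020,0.00087,0.40,0.69
favg_al,intercept,1.17,1.06,1.29,0.058,20.28,5.83e-14
favg_al,model [Sprinter],0.14,0.066,0.21,0.036,3.78,0.00017
favg_al,model [Xtend],0.12,0.050,0.19,0.036,3.34,0.00089
favg_al,stiffness cat [Rec],0.0035,-0.066,0.073,0.036,0.10,0.92
favg_al,stiffness cat [+1],0.076,0.0051,0.15,0.037,2.09,0.037
favg_al,height [cm],-0.022,-0.046,0.0022,0.012,-1.77,0.077
favg_al,speed [m s^-1],0.078,0.066,0.090,0.0062,12.56,2e-16
favg_al,model [Sprinter]*speed [m s^-1],0.00050,-0.013,0.014,0.0070,0.072,0.94
favg_al,model [Xtend]*speed [m s^-1],0.0095,-0.0042,0.023,0.0071,1.35,0.18
favg_al,stiffness cat [Rec]*speed [m s^-1],0.0025,-0.011,0.016,0.0069,0.37,0.72
favg_al,stiffness cat [+1]*speed [m s^-1],-0.0057,-0.020,0.0082,0.0071,-0.80,0.43
favg_al,height [cm]*speed [m s^-1],-0.0023,-0.0070,0.0024,0.0024,-0.97,0.33
fstep_al,intercept,2.12,1.97,2.27,0.079,26.84,2e-16
fstep_al,model [Sprinter],-0.23,-0.35,-0.11,0.061,-3.75,0.00019
fstep_al,model [Xtend],-0.13,-0.25,-0.015,0.061,-2.19,0.029
fstep_al,stiffness cat [Rec],0.093,-0.025,0.21,0.060,1.54,0.12
fstep_al,stiffness cat [+1],0.12,0.00021,0.24,0.062,1.95,0.052
fstep_al,height [cm],-0.015,-0.056,0.026,0.021,-0.72,0.47
fstep_al,speed [m s^-1],0.27,0.25,0.29,0.010,26.14,2e-16
fstep_al,model [Sprinter]*speed [m s^-1],0.022,-0.00070,0.045,0.012,1.89,0.060
fstep_al,model [Xtend]*speed [m s^-1],0.0025,-0.021,0.026,0.012,0.21,0.83
fstep_al,stiffness cat [Rec]*speed [m s^-1],-0.024,-0.047,-0.0014,0.012,-2.07,0.039
fstep_al,stiffness cat [+1]*speed [m s^-1],-0.026,-0.050,-0.0030,0.012,-2.20,0.029
fstep_al,height [cm]*speed [m s^-1],-0.0061,-0.014,0.0018,0.0041,-1.50,0.13
si_lc,intercept,-6.08,-9.50,-2.66,1.75,-3.48,0.0016
si_lc,model [Sprinter],-0.24,-2.82,2.34,1.32,-0.18,0.86
si_lc,model [Xtend],6.90,4.31,9.48,1.33,5.20,2.69e-7
si_lc,stiffness cat [Rec],4.72,2.17,7.27,1.31,3.61,0.00033
si_lc,stiffness cat [+1],6.40,3.79,9.01,1.34,4.78,2.17e-6
si_lc,height [cm],-2.07,-2.95,-1.19,0.45,-4.57,5.86e-6
si_lc,speed [m s^-1],0.14,-0.31,0.58,0.23,0.60,0.55
si_lc,model [Sprinter]*speed [m s^-1],-0.29,-0.79,0.21,0.26,-1.12,0.26
si_lc,model [Xtend]*speed [m s^-1],-0.81,-1.31,-0.30,0.26,-3.11,0.0020
si_lc,stiffness cat [Rec]*speed [m s^-1],-0.46,-0.95,0.035,0.25,-1.81,0.071
si_lc,stiffness cat [+1]*speed [m s^-1],-0.43,-0.94,0.074,0.26,-1.67,0.096
si_lc,height [cm]*speed [m s^-1],0.13,-0.045,0.30,0.088,1.43,0.15
si_favg,intercept,15.03,9.78,20.28,2.71,5.55,4.33e-7
si_favg,model [Sprinter],-10.07,-14.97,-5.17,2.52,-4.00,7.00e-5
si_favg,model [Xtend],-5.42,-10.33,-0.51,2.52,-2.15,0.032
si_favg,stiffness cat [Rec],0.77,-4.07,5.61,2.49,0.31,0.76
si_favg,stiffness cat [+1],-1.18,-6.14,3.78,2.55,-0.46,0.64
si_favg,height [cm],3.86,2.18,5.53,0.86,4.48,8.58e-6
si_favg,speed [m s^-1],-0.054,-0.89,0.78,0.43,-0.13,0.90
si_favg,model [Sprinter]*speed [m s^-1],-0.061,-1.01,0.89,0.49,-0.13,0.90
si_favg,model [Xtend]*speed [m s^-1],-0.94,-1.90,0.020,0.49,-1.91,0.057
si_favg,stiffness cat [Rec]*speed [m s^-1],-0.053,-0.99,0.88,0.48,-0.11,0.91
si_favg,stiffness cat [+1]*speed [m s^-1],0.24,-0.72,1.21,0.49,0.49,0.62
si_favg,height [cm]*speed [m s^-1],0.088,-0.24,0.41,0.17,0.53,0.60
si_fstep,intercept,-2.32,-5.60,0.97,1.70,-1.37,0.17
si_fstep,model [Sprinter],5.23,1.78,8.69,1.78,2.94,0.0034
si_fstep,model [Xtend],2.99,-0.48,6.46,1.78,1.68,0.094
si_fstep,stiffness cat [Rec],-1.03,-4.45,2.40,1.76,-0.58,0.56
si_fstep,stiffness cat [+1],-2.79,-6.30,0.71,1.80,-1.55,0.12
si_fstep,height [cm],1.98,0.80,3.17,0.61,3.27,0.0011
si_fstep,speed [m s^-1],0.75,0.16,1.35,0.30,2.48,0.013
si_fstep,model [Sprinter]*speed [m s^-1],-0.89,-1.56,-0.22,0.34,-2.59,0.0098
si_fstep,model [Xtend]*speed [m s^-1],-0.25,-0.93,0.43,0.35,-0.72,0.47
si_fstep,stiffness cat [Rec]*speed [m s^-1],0.57,-0.092,1.23,0.34,1.68,0.094
si_fstep,stiffness cat [+1]*speed [m s^-1],0.89,0.21,1.57,0.35,2.54,0.011
si_fstep,height [cm]*speed [m s^-1],0.10,-0.13,0.33,0.12,0.87,0.39
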
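set,name,q,p,lssc_min,lsc_min,dg_min,error
varHP,PP01,-2,18.07,0.59,-6.7,-37.7,5.0
varHP,PP02,-2,18.14,0.56,-5.7,-36.1,3.6
varHP,PP03,-2,18.04,0.37,-12.2,-34.5,4.9
varHP,PP04,-2,17.98,0.58,-14.0,-28.9,4.8
varHP,PP05,-2,18.00,0.66,-13.1,-34.1,4.6
varHP,PP06,-2,18.32,0.45,-9.2,-36.2,4.2
varHP,PP07,-2,17.86,0.59,-4.1,-31.7,1.9
varHP,PP08,-2,18.08,0.67,-3.9,-29.4,2.0
varHP,PP09,-2,18.15,0.61,-11.5,-17.6,4.5
varHP,PP10,-2,18.20,0.31,-8.4,-30.1,3.9
varHP,PP11,-2,17.76,0.54,-10.9,-30.8,4.3
varHP,PP12,-2,17.92,0.58,-4.8,-28.7,1.6
varQ,PP07,-2,17.86,0.59,-4.1,-31.3,1.7
varQ,PP13,-6,18.27,0.59,-4.1,-7.7,3.9
varQ,PP14,-10,18.71,0.59,-4.1,16.0,1.8
varD,PP15,-2,0.65,0.57,-1.9,-31.4,1.4
varD,PP07,-2,17.86,0.59,-4.1,-31.8,1.7
varD,PP16,-2,35.08,0.55,-8.9,-33.9,1.6
varD,PP17,-2,55.53,0.72,-11.5,-36.5,4.1
varD,PP18,-2,65.75,0.80,-17.1,-52.1,5.8
varD,PP19,-2,71.95,0.68,-32.6,-79.0,10.3
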
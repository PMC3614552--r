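set,descriptor,c1,c2,c3,r2,p_value
setA,p,-0.329,4.339,91.09,0.63,5.82e-04
setA,nsap,992.9,2.396,31.30,0.33,4.91e-02
setA,sapmax,7.819,1.714,37.35,0.31,6.37e-02
setA,ccsol,NA,NA,NA,0.43,NA
setB,p,-2.671,57.43,226.3,0.62,2.58e-04
setB,nsap,-1317.5,14.29,51.68,0.41,1.16e-02
setB,sapmax,-8.403,18.02,33.51,0.29,5.13e-02
setB,ccsol,NA,NA,NA,0.16,NA
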
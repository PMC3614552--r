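id,class,mutation,q0,dq,p0,dp
1AXI,cytokine,R134D,-5.0,-2.0,94.8,-43.5
1IL6,cytokine,R15D,-1.0,-2.0,82.5,-57.0
1RW5,cytokine,R16D,-3.0,-2.0,99.0,-46.1
1CNT,cytokine,R189D,-3.0,-2.0,67.8,-48.0
1BGC,cytokine,R51D,-2.0,-2.0,45.9,-23.5
1F6F,cytokine,D162R,4.0,2.0,140.5,-53.5
2ILK,cytokine,D44R,1.0,2.0,154.4,-51.1
1AU1,cytokine,E107R,4.0,2.0,65.6,-22.2
1BBN,cytokine,E110R,7.0,2.0,64.2,-27.5
1M4R,cytokine,E124R,1.0,2.0,85.3,-39.8
1D9C,cytokine,E13R,8.0,2.0,265.9,-54.8
1LKI,cytokine,E154R,7.0,2.0,101.6,-50.6
1HUL,cytokine,E29R,0.0,3.0,72.8,-32.3
1EER,cytokine,E37R,3.0,2.0,87.4,-36.6
1JLI,cytokine,E43R,0.0,2.0,47.5,-14.9
1GA3,cytokine,E58R,3.0,2.0,22.4,-6.8
1EVS,cytokine,E99R,12.0,2.0,201.5,-56.4
1B5L,cytokine,K164D,-8.0,-2.0,126.8,-26.0
2HYM,cytokine,K31D,-2.0,-2.0,114.5,-42.4
1AX8,cytokine,K5D,-3.0,-2.0,43.7,-10.0
2GMF,cytokine,K72D,-5.0,-2.0,143.5,-28.7
1IRL,cytokine,K76D,-0.0,-2.0,101.0,-41.1
1HZH,antibody,D423R,26.0,2.0,345.5,-133.1
1IGT,antibody,D31R,5.0,1.0,264.8,-82.3
1IGY,antibody,D352R,4.0,0.0,763.2,-128.1
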
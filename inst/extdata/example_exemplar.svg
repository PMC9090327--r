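<svg xmlns="http://www.w3.org/2000/svg" width="400" height="400">
<polygon points="330.45,204.52 332.90,220.39 335.74,236.20 337.95,252.10 338.65,268.13 337.12,284.10 332.76,299.53 325.21,313.66 317.20,327.09 319.53,342.95 322.35,358.76 321.70,374.68 308.62,380.00 294.65,372.21 282.28,361.98 270.49,351.08 257.71,341.48 241.94,338.58 226.47,334.28 211.22,329.25 195.82,324.70 180.03,321.83 164.03,320.54 148.01,319.41 132.14,317.01 116.80,312.32 102.68,304.74 90.65,294.17 81.48,281.03 75.48,266.17 72.42,250.42 71.64,234.39 72.24,218.35 59.98,210.73 44.17,207.90 28.45,204.67 20.00,196.97 35.59,193.33 51.53,191.37 67.42,189.13 74.48,177.26 75.17,161.22 76.70,145.24 79.85,129.50 85.27,114.41 93.37,100.57 104.19,88.75 117.34,79.59 132.14,73.42 147.84,70.17 163.87,69.38 179.89,70.41 195.82,72.46 211.71,74.74 227.56,75.81 236.17,62.46 242.89,47.87 249.91,33.43 258.62,20.00 264.18,30.00 262.54,45.97 260.19,61.86 259.04,77.83 272.31,84.81 287.09,91.05 300.38,100.01 311.38,111.66 319.52,125.47 324.70,140.64 327.39,156.46 328.45,172.48 329.08,188.53" fill="none" stroke="black" stroke-width="1"/>
</svg>
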
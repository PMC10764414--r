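province,region,meta,group
Beijing,East,0.995,0.995
Tianjin,East,1.000,1.000
Hebei,East,0.880,0.899
Liaoning,East,0.572,0.593
Shanghai,East,1.000,1.000
Jiangsu,East,0.987,0.989
Zhejiang,East,1.000,1.000
Fujian,East,1.000,1.000
Shandong,East,0.873,0.902
Guangdong,East,1.000,1.000
Hainan,East,1.000,1.000
Shanxi,Central,0.620,0.967
Jilin,Central,0.581,1.000
Heilongjiang,Central,0.465,0.980
Anhui,Central,0.913,1.000
Jiangxi,Central,0.993,1.000
Henan,Central,0.994,1.000
Hubei,Central,0.874,0.990
Hunan,Central,0.773,0.948
Inner Mongolia,West,0.570,0.686
Guangxi,West,0.987,1.000
Chongqing,West,0.950,1.000
Sichuan,West,0.908,1.000
Guizhou,West,0.883,1.000
Yunnan,West,0.934,1.000
Shaanxi,West,0.615,0.748
Gansu,West,0.892,0.969
Qinghai,West,1.000,1.000
Ningxia,West,1.000,1.000
Xinjiang,West,0.578,0.688
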
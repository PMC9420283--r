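outcome_id,exposure_category,pr,pf_pct,parp_pct,preventable_dalys,attributable_dalys,known_discrepancy
breast_cancer,total_dairy,0.15,2.25,2.58,29070,33318.1,
breast_cancer,total_dairy,0.25,3.75,4.23,48450,54591.5,
breast_cancer,total_dairy,0.35,5.25,5.82,67830,75157.9,
breast_cancer,total_dairy,0.5,7.5,8.11,96900,104756.8,
colorectal_cancer,total_dairy,0.15,2.55,2.98,35638.8,41658.4,
colorectal_cancer,total_dairy,0.25,4.25,4.87,59398,68077.9,
colorectal_cancer,total_dairy,0.35,5.95,6.69,83157.2,93487.6,
colorectal_cancer,total_dairy,0.5,8.5,9.29,118796,129831.7,
cvd,total_dairy,0.15,1.5,1.64,253506,277055.7,
cvd,total_dairy,0.25,2.5,2.7,422510,456767.6,
cvd,total_dairy,0.35,3.5,3.74,591514,632635.3,
cvd,total_dairy,0.5,5,5.26,845020,889494.7,
t2d,total_dairy,0.15,1.35,1.46,57713.9,62494.7,
t2d,total_dairy,0.25,2.25,2.41,96189.8,103152.5,
t2d,total_dairy,0.35,3.15,3.35,134665.7,143033.1,
t2d,total_dairy,0.5,4.5,4.71,192379.5,201444.5,
stroke,total_dairy,0.15,1.8,2,62523,69624.7,
stroke,total_dairy,0.25,3,3.3,104205,114511,
stroke,total_dairy,0.35,4.2,4.56,145887,158228.9,
stroke,total_dairy,0.5,6,6.38,208410,221712.8,
hypertension,total_dairy,0.15,1.65,1.82,22149.6,24434.2,
hypertension,total_dairy,0.25,2.75,3,36916,40235.4,
hypertension,total_dairy,0.35,3.85,4.15,51682.4,55662.3,
hypertension,total_dairy,0.5,5.5,5.82,73832,78129.1,
colorectal_cancer,milk,0.15,2.85,3.4,39831.6,47503.4,
colorectal_cancer,milk,0.25,4.75,5.54,66386,77418.1,
colorectal_cancer,milk,0.35,6.65,7.59,92940.4,106035.8,
colorectal_cancer,milk,0.5,9.5,10.5,132772,146709.4,
t2d,milk,0.15,1.95,2.19,83364.5,93720.6,
t2d,milk,0.25,3.25,3.6,138940.8,153951,
t2d,milk,0.35,4.55,4.97,194517.1,212470.8,
t2d,milk,0.5,6.5,6.95,277881.5,297199.5,
breast_cancer,low_fat_dairy,0.15,2.4,2.78,31008,35888.9,
breast_cancer,low_fat_dairy,0.25,4,4.55,51680,58727.3,
breast_cancer,low_fat_dairy,0.35,4.8,6.25,62016,80750,pf_pct;preventable_dalys
breast_cancer,low_fat_dairy,0.5,8,8.7,103360,112347.8,
t2d,low_fat_dairy,0.15,2.55,2.98,109015.1,127428.5,
t2d,low_fat_dairy,0.25,4.25,4.87,181691.8,208242.7,
t2d,low_fat_dairy,0.35,5.95,6.69,254368.5,285967.9,
t2d,low_fat_dairy,0.5,8.5,9.29,363383.5,397140.4,
stroke,low_fat_dairy,0.15,0.9,0.95,31261.5,32941.5,
stroke,low_fat_dairy,0.25,1.5,1.57,52102.5,54557.6,
stroke,low_fat_dairy,0.35,2.1,2.19,72943.5,75903.7,
stroke,low_fat_dairy,0.5,3,3.09,104205,107427.8,
hypertension,low_fat_dairy,0.15,2.4,2.78,32217.6,37288.9,
hypertension,low_fat_dairy,0.25,4,4.55,53696,61018.2,
hypertension,low_fat_dairy,0.35,5.6,6.25,75174.4,83900,
hypertension,low_fat_dairy,0.5,8,8.7,107392,116730.4,
colorectal_cancer,high_fat_dairy,0.15,4.8,6.59,67084.8,92149.5,
colorectal_cancer,high_fat_dairy,0.25,8,10.53,111808,147115.8,
colorectal_cancer,high_fat_dairy,0.35,11.2,14.14,156531.2,197640.4,
colorectal_cancer,high_fat_dairy,0.5,16,19.05,223616,266209.5,
stroke,high_fat_dairy,0.15,1.35,1.46,46892.3,50776.7,
stroke,high_fat_dairy,0.25,2.25,2.41,78153.8,83811,
stroke,high_fat_dairy,0.35,3.15,3.35,109415.3,116213.8,
stroke,high_fat_dairy,0.5,4.5,4.71,156307.5,163672.8,
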
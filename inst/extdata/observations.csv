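strain,N,basis,quantity,value,flag,note
WT,1,data,alpha,0.18,ok,
WT,1,data,Fe_cell,120,ok,
WT,1,data,R_cell,22,ok,alpha*Fe_cell=21.6
WT,1,data,fFe_cyt,79,ok,
WT,1,data,fFe_mit,41,ok,
WT,1,data,fFe_vac,0,discrepant,conflicts with F2=600 in the pool table for the same condition
WT,1,data,R_cyt_only,18,ok,
WT,1,data,R_mit,9.2,ok,
WT,1,data,R_vac,0,discrepant,zero follows from the zero vacuole entry
WT,1,data,C,2.5,ok,
WT,1,data,CIA,92,ok,
WT,1,data,FM,60,ok,
WT,1,data,FS,320,ok,
WT,1,data,MP,0,ok,
WT,1,data,F2,600,discrepant,conflicts with zero vacuolar iron in the rate table
WT,1,data,F3,0,ok,
WT,1,data,VP,0,ok,
WT,2,data,alpha,0.18,ok,
WT,2,data,Fe_cell,200,ok,
WT,2,data,R_cell,37,ok,
WT,2,data,fFe_cyt,75,ok,
WT,2,data,fFe_mit,43,ok,
WT,2,data,fFe_vac,82,ok,
WT,2,data,R_cyt_only,17,ok,
WT,2,data,R_mit,9.9,ok,
WT,2,data,R_vac,19,ok,
WT,2,data,C,3,ok,
WT,2,data,CIA,84,ok,
WT,2,data,FM,80,ok,
WT,2,data,FS,290,ok,
WT,2,data,MP,60,ok,
WT,2,data,F2,96,ok,
WT,2,data,F3,780,ok,
WT,2,data,VP,0,ok,
WT,11,data,alpha,0.20,ok,
WT,11,data,Fe_cell,480,ok,
WT,11,data,R_cell,97,ok,
WT,11,data,fFe_cyt,200,ok,
WT,11,data,fFe_mit,56,ok,
WT,11,data,fFe_vac,220,ok,
WT,11,data,R_cyt_only,52,ok,
WT,11,data,R_mit,14,ok,
WT,11,data,R_vac,56,ok,
WT,11,data,C,4,ok,
WT,11,data,CIA,250,ok,
WT,11,data,FM,140,ok,
WT,11,data,FS,380,ok,
WT,11,data,MP,30,ok,
WT,11,data,F2,320,ok,
WT,11,data,F3,1900,ok,
WT,11,data,VP,0,ok,
WT,41,data,alpha,0.20,ok,
WT,41,data,Fe_cell,880,ok,
WT,41,data,R_cell,180,ok,
WT,41,data,fFe_cyt,310,ok,
WT,41,data,fFe_mit,69,ok,
WT,41,data,fFe_vac,500,ok,
WT,41,data,R_cyt_only,77,ok,
WT,41,data,R_mit,18,ok,
WT,41,data,R_vac,130,ok,
WT,41,data,C,5,ok,
WT,41,data,CIA,380,ok,
WT,41,data,FM,210,ok,
WT,41,data,FS,480,ok,
WT,41,data,MP,0,ok,
WT,41,data,F2,450,ok,
WT,41,data,F3,4600,ok,
WT,41,data,VP,0,ok,
DD,1,data,alpha,0.06,ok,
DD,1,data,Fe_cell,360,ok,
DD,1,data,R_cell,22,ok,
DD,1,data,fFe_cyt,110,ok,
DD,1,data,fFe_mit,69,ok,
DD,1,data,fFe_vac,180,ok,
DD,1,data,R_cyt_only,8.1,ok,
DD,1,data,R_mit,5.2,ok,
DD,1,data,R_vac,14,ok,
DD,1,data,C,3,ok,
DD,1,data,CIA,130,ok,
DD,1,data,FM,60,ok,
DD,1,data,FS,40,ok,
DD,1,data,MP,530,ok,
DD,1,data,F2,1400,reconstructed,digit lost in source extraction; sum with F3 matches compartment total exactly
DD,1,data,F3,400,reconstructed,digit lost in source extraction; sum with F2 matches compartment total exactly
DD,1,data,VP,0,ok,
DD,2,data,alpha,0.068,ok,
DD,2,data,Fe_cell,680,ok,
DD,2,data,R_cell,46,ok,
DD,2,data,fFe_cyt,130,ok,
DD,2,data,fFe_mit,69,ok,
DD,2,data,fFe_vac,480,ok,
DD,2,data,R_cyt_only,11,ok,
DD,2,data,R_mit,5.9,ok,
DD,2,data,R_vac,41,ok,
DD,2,data,C,4,ok,
DD,2,data,CIA,160,ok,
DD,2,data,FM,60,ok,
DD,2,data,FS,40,ok,
DD,2,data,MP,530,ok,
DD,2,data,F2,1300,ok,
DD,2,data,F3,3400,ok,
DD,2,data,VP,170,ok,
DD,11,data,alpha,0.15,ok,
DD,11,data,Fe_cell,2200,ok,
DD,11,data,R_cell,320,ok,
DD,11,data,fFe_cyt,280,ok,
DD,11,data,fFe_mit,72,ok,
DD,11,data,fFe_vac,1800,ok,
DD,11,data,R_cyt_only,52,ok,
DD,11,data,R_mit,13,ok,
DD,11,data,R_vac,340,ok,
DD,11,data,C,8,ok,
DD,11,data,CIA,340,ok,
DD,11,data,FM,85,ok,
DD,11,data,FS,300,ok,
DD,11,data,MP,300,ok,
DD,11,data,F2,950,ok,
DD,11,data,F3,11000,ok,
DD,11,data,VP,6400,ok,
DD,41,data,alpha,0.20,ok,
DD,41,data,Fe_cell,3900,ok,
DD,41,data,R_cell,800,ok,
DD,41,data,fFe_cyt,230,ok,
DD,41,data,fFe_mit,74,ok,
DD,41,data,fFe_vac,3600,ok,
DD,41,data,R_cyt_only,59,ok,
DD,41,data,R_mit,19,ok,
DD,41,data,R_vac,920,ok,
DD,41,data,C,10,ok,
DD,41,data,CIA,280,ok,
DD,41,data,FM,110,ok,
DD,41,data,FS,560,ok,
DD,41,data,MP,80,ok,
DD,41,data,F2,1000,ok,
DD,41,data,F3,22000,ok,
DD,41,data,VP,13000,ok,
WT,1,sim,alpha,0.18,ok,
WT,1,sim,Fe_cell,60,ok,
WT,1,sim,R_cell,10,ok,
WT,1,sim,fFe_cyt,22,ok,
WT,1,sim,fFe_mit,22,ok,
WT,1,sim,fFe_vac,16,ok,
WT,1,sim,R_cyt_only,5.0,ok,
WT,1,sim,R_mit,4.9,ok,
WT,1,sim,R_vac,3.7,ok,
WT,1,sim,C,1.5,ok,
WT,1,sim,CIA,16,ok,
WT,1,sim,FM,110,ok,
WT,1,sim,FS,160,ok,
WT,1,sim,MP,90,ok,
WT,1,sim,F2,14,ok,
WT,1,sim,F3,85,ok,
WT,1,sim,VP,0,ok,
WT,2,sim,alpha,0.19,ok,
WT,2,sim,Fe_cell,190,ok,
WT,2,sim,R_cell,35,ok,
WT,2,sim,fFe_cyt,76,ok,
WT,2,sim,fFe_mit,35,ok,
WT,2,sim,fFe_vac,81,ok,
WT,2,sim,R_cyt_only,18,ok,
WT,2,sim,R_mit,8.4,ok,
WT,2,sim,R_vac,19,ok,
WT,2,sim,C,2.7,ok,
WT,2,sim,CIA,79,ok,
WT,2,sim,FM,190,ok,
WT,2,sim,FS,380,ok,
WT,2,sim,MP,62,ok,
WT,2,sim,F2,43,ok,
WT,2,sim,F3,590,ok,
WT,2,sim,VP,2.6,ok,
WT,11,sim,alpha,0.20,ok,
WT,11,sim,Fe_cell,810,ok,
WT,11,sim,R_cell,160,ok,
WT,11,sim,fFe_cyt,180,ok,
WT,11,sim,fFe_mit,66,ok,
WT,11,sim,fFe_vac,560,ok,
WT,11,sim,R_cyt_only,45,ok,
WT,11,sim,R_mit,17,ok,
WT,11,sim,R_vac,140,ok,
WT,11,sim,C,5.6,ok,
WT,11,sim,CIA,210,ok,
WT,11,sim,FM,430,ok,
WT,11,sim,FS,730,ok,
WT,11,sim,MP,71,ok,
WT,11,sim,F2,250,ok,
WT,11,sim,F3,NA,unparsed,printed digits are inconsistent with the compartment sum
WT,11,sim,VP,320,ok,
WT,41,sim,alpha,0.20,ok,
WT,41,sim,Fe_cell,900,ok,
WT,41,sim,R_cell,180,ok,
WT,41,sim,fFe_cyt,180,ok,
WT,41,sim,fFe_mit,69,ok,
WT,41,sim,fFe_vac,640,ok,
WT,41,sim,R_cyt_only,46,ok,
WT,41,sim,R_mit,18,ok,
WT,41,sim,R_vac,160,ok,
WT,41,sim,C,6.0,ok,
WT,41,sim,CIA,220,ok,
WT,41,sim,FM,470,ok,
WT,41,sim,FS,750,ok,
WT,41,sim,MP,75,ok,
WT,41,sim,F2,290,ok,
WT,41,sim,F3,5200,ok,
WT,41,sim,VP,440,ok,
DD,1,sim,alpha,0.05,discrepant,Michaelis-Menten growth law gives 0.042 at these parameters
DD,1,sim,Fe_cell,540,ok,
DD,1,sim,R_cell,27,ok,
DD,1,sim,fFe_cyt,240,ok,
DD,1,sim,fFe_mit,74,ok,
DD,1,sim,fFe_vac,230,ok,
DD,1,sim,R_cyt_only,13,ok,
DD,1,sim,R_mit,3.9,ok,
DD,1,sim,R_vac,12,ok,
DD,1,sim,C,2.6,ok,
DD,1,sim,CIA,310,ok,
DD,1,sim,FM,3.6,ok,
DD,1,sim,FS,0.8,ok,
DD,1,sim,MP,580,ok,
DD,1,sim,F2,2300,ok,
DD,1,sim,F3,57,ok,
DD,1,sim,VP,0.6,ok,
DD,2,sim,alpha,0.069,ok,
DD,2,sim,Fe_cell,1100,ok,
DD,2,sim,R_cell,90,discrepant,alpha*Fe_cell gives 76 at these entries
DD,2,sim,fFe_cyt,380,ok,
DD,2,sim,fFe_mit,77,ok,
DD,2,sim,fFe_vac,660,ok,
DD,2,sim,R_cyt_only,33,ok,
DD,2,sim,R_mit,6.6,ok,
DD,2,sim,R_vac,58,ok,
DD,2,sim,C,4.3,ok,
DD,2,sim,CIA,470,ok,
DD,2,sim,FM,100,ok,
DD,2,sim,FS,350,ok,
DD,2,sim,MP,140,ok,
DD,2,sim,F2,180,ok,
DD,2,sim,F3,4600,ok,
DD,2,sim,VP,2000,ok,
DD,11,sim,alpha,0.15,ok,
DD,11,sim,Fe_cell,2300,ok,
DD,11,sim,R_cell,360,ok,
DD,11,sim,fFe_cyt,280,ok,
DD,11,sim,fFe_mit,71,ok,
DD,11,sim,fFe_vac,1900,ok,
DD,11,sim,R_cyt_only,53,ok,
DD,11,sim,R_mit,13,ok,
DD,11,sim,R_vac,360,ok,
DD,11,sim,C,8.6,ok,
DD,11,sim,CIA,340,ok,
DD,11,sim,FM,150,ok,
DD,11,sim,FS,330,ok,
DD,11,sim,MP,70,ok,
DD,11,sim,F2,1200,ok,
DD,11,sim,F3,11000,ok,
DD,11,sim,VP,7500,ok,
DD,41,sim,alpha,0.19,ok,
DD,41,sim,Fe_cell,2000,ok,
DD,41,sim,R_cell,390,ok,
DD,41,sim,fFe_cyt,230,ok,
DD,41,sim,fFe_mit,61,ok,
DD,41,sim,fFe_vac,1800,ok,
DD,41,sim,R_cyt_only,54,ok,
DD,41,sim,R_mit,14,ok,
DD,41,sim,R_vac,410,ok,
DD,41,sim,C,9.2,ok,
DD,41,sim,CIA,280,ok,
DD,41,sim,FM,140,ok,
DD,41,sim,FS,260,ok,
DD,41,sim,MP,71,ok,
DD,41,sim,F2,1600,ok,
DD,41,sim,F3,10000,ok,
DD,41,sim,VP,5700,ok,
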
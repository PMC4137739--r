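no,compound,brpp,ha_pred,ha_resid,svm_pred,svm_resid,split
1,Acebutolol,26.0,35.9,9.9,40.0,14.0,test
2,Alprenolol,85.0,61.5,-23.5,72.9,-12.1,train
3,Amantadine,67.0,58.6,-8.4,61.9,-5.1,train
4,Amiodarone,100.0,110.9,10.9,100.3,0.3,train
5,Amitriptyline,94.8,100.1,5.3,90.1,-4.7,train
6,Aspirin,49.0,56.1,7.1,45.0,-4.0,test
7,Betamethasone,64.0,62.9,-1.1,61.0,-3.0,train
8,Bumetanide,99.0,92.6,-6.4,94.0,-5.0,train
9,Caffeine,36.0,28.0,-8.0,30.9,-5.1,train
10,Cefalexin,14.0,41.6,27.6,41.0,27.0,train
11,Chloroquine,61.0,67.7,6.7,75.6,14.6,test
12,Chlorthalidone,75.0,76.8,1.8,80.0,5.0,train
13,Cimetidine,19.0,17.2,-1.8,19.4,0.4,train
14,Ciprofloxacin,40.0,40.6,0.6,43.4,3.4,train
15,Diphenhydramine,78.0,83.2,5.2,83.9,5.9,train
16,Furosemide,98.8,85.8,-13.0,95.5,-3.3,test
17,Glibenclamide,99.0,114.0,15.0,95.1,-3.9,train
18,Haloperidol,92.0,91.3,-0.7,95.7,3.7,train
19,Lidocaine,70.0,60.6,-9.4,75.1,5.1,train
20,Methadone,89.0,94.3,5.3,94.0,5.0,train
21,Methotrexate,34.0,47.3,13.3,53.4,19.4,test
22,Metoclopramide,40.0,37.4,-2.6,44.3,4.3,train
23,Metronidazole,10.0,16.1,6.1,15.0,5.0,train
24,Nifedipine,96.0,91.0,-5.0,96.6,0.6,train
25,Phenobarbital,51.0,60.4,9.4,46.2,-4.8,train
26,Pindoioi,51.0,53.6,2.6,69.0,18.0,test
27,Prednisone,75.0,58.0,-17.0,69.9,-5.1,train
28,Quinidine,87.0,93.8,6.8,100.0,13.0,train
29,Ranitidine,15.0,15.7,0.7,15.6,0.6,train
30,Sulfadiazine,54.0,65.6,11.6,59.1,5.1,train
31,Sulfamethoxazole,62.0,56.4,-5.6,48.1,-13.9,test
32,Terbutaline,20.0,39.2,19.2,25.1,5.1,train
33,Timolol,60.0,44.6,-15.4,65.1,5.1,train
34,Triamterene,61.0,58.9,-2.1,66.1,5.1,train
35,Amikacin,4.0,-12.4,-16.4,5.4,1.4,train
36,Carbamazepine,74.0,72.2,-1.8,81.8,7.8,test
37,Carbenicillin,50.0,63.9,13.9,55.0,5.0,train
38,Cefamandole,74.0,78.7,4.7,76.1,2.1,train
39,Cefazolin,89.0,72.4,-16.6,83.9,-5.1,train
40,Cefotaxime,36.0,37.1,1.1,33.6,-2.4,train
41,Cefuroxime,33.0,52.6,19.6,53.4,20.4,test
42,Chloramphenicol,53.0,37.7,-15.3,47.9,-5.1,train
43,Chlorothiazide,94.6,83.2,-11.4,89.5,-5.1,train
44,Clonazepam,86.0,83.1,-2.9,80.9,-5.1,train
45,Cocaine,91.0,82.2,-8.8,85.9,-5.1,train
46,Dapsone,73.0,69.0,-4.0,66.6,-6.4,test
47,Dexamethasone,68.0,78.9,10.9,73.1,5.1,train
48,Diazepam,98.7,88.7,-10.0,93.6,-5.1,train
49,Ethinylestradiol,98.0,86.2,-11.8,92.9,-5.1,train
50,Famotidine,17.0,16.2,-0.8,11.9,-5.1,train
51,Fentanyl,84.0,85.8,1.8,90.2,6.2,test
52,Flecainide,61.0,80.6,19.6,66.0,5.0,train
53,Hydrochlorothiazide,58.0,57.6,-0.4,63.0,5.0,train
54,Imipramine,90.1,93.6,3.5,85.0,-5.1,train
55,Isoniazid,0.0,17.4,17.4,5.1,5.1,train
56,Isosorbide-5-mononitrate,0.0,10.7,10.7,-11.8,-11.8,test
57,Ketoconazole,99.0,90.4,-8.6,104.1,5.1,train
58,Lovastatin,95.0,101.3,6.3,100.0,5.0,train
59,Mexiletine,63.0,66.3,3.3,68.1,5.1,train
60,Nitrazepam,87.0,97.1,10.1,94.6,7.6,train
61,Norethisterone,80.0,76.1,-3.9,88.3,8.3,test
62,Omeprazole,95.0,89.9,-5.1,92.6,-2.4,train
63,Pethidine,58.0,72.0,14.0,76.3,18.3,train
64,Phenylbutazone,96.1,104.5,8.4,101.2,5.1,train
65,Propafenone,97.0,79.6,-17.4,91.0,-6.0,train
66,Propranolol,87.0,83.4,-3.6,90.3,3.3,test
67,Pyrimethamine,87.0,69.2,-17.8,79.8,-7.2,train
68,Thiopental,85.0,76.8,-8.2,79.9,-5.1,train
69,Ticarcillin,65.0,50.7,-14.3,59.9,-5.1,train
70,Warfarin,99.0,88.0,-11.0,94.0,-5.0,train
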
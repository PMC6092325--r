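month,n_predators,taxon,mean,se,flag
Nov,23,siphonophores,0.04,0.04,0
Nov,23,pteropods,0.70,0.21,+
Nov,23,ostracods,0.04,0.04,0
Nov,23,furcilia,0,0,0
Nov,23,fish_larvae,0.04,0.04,0
Nov,23,fish_eggs,0.52,0.16,+
Nov,23,copepods,12.34,3.45,+
Nov,23,chaetognaths,0.43,0.19,0
Nov,23,appendicularians,0.04,0.04,0
Dec,17,siphonophores,0,0,0
Dec,17,pteropods,7.71,3.65,0
Dec,17,ostracods,0,0,-
Dec,17,furcilia,0,0,0
Dec,17,fish_larvae,0.06,0.05,0
Dec,17,fish_eggs,0.41,0.12,+
Dec,17,copepods,6.65,2.62,0
Dec,17,chaetognaths,0.60,0.32,+
Dec,17,appendicularians,0,0,0
Feb,3,siphonophores,0,0,0
Feb,3,pteropods,0,0,0
Feb,3,ostracods,0,0,0
Feb,3,furcilia,0,0,0
Feb,3,fish_larvae,0,0,0
Feb,3,fish_eggs,0,0,0
Feb,3,copepods,0.33,0.33,0
Feb,3,chaetognaths,0,0,0
Feb,3,appendicularians,0,0,0
Apr,12,siphonophores,0,0,0
Apr,12,pteropods,0.22,0.22,0
Apr,12,ostracods,0.11,0.11,0
Apr,12,furcilia,0,0,-
Apr,12,fish_larvae,0,0,0
Apr,12,fish_eggs,1.33,0.57,0
Apr,12,copepods,36.66,8.17,0
Apr,12,chaetognaths,0,0,0
Apr,12,appendicularians,0.11,0.11,0
May,20,siphonophores,0,0,0
May,20,pteropods,0.45,0.35,0
May,20,ostracods,0.1,0.06,0
May,20,furcilia,0.05,0.05,0
May,20,fish_larvae,0,0,0
May,20,fish_eggs,0.80,0.22,+
May,20,copepods,21.95,5.79,+
May,20,chaetognaths,1.35,0.70,0
May,20,appendicularians,0.20,0.15,0
Jun,27,siphonophores,0,0,0
Jun,27,pteropods,0.26,0.11,0
Jun,27,ostracods,0,0,0
Jun,27,furcilia,0,0,0
Jun,27,fish_larvae,0.04,0.03,0
Jun,27,fish_eggs,0.52,0.16,+
Jun,27,copepods,10.37,1.99,+
Jun,27,chaetognaths,0.22,0.12,0
Jun,27,appendicularians,0.07,0.05,0
Jul,13,siphonophores,0,0,0
Jul,13,pteropods,0,0,0
Jul,13,ostracods,0.08,0.07,0
Jul,13,furcilia,0,0,0
Jul,13,fish_larvae,0.08,0.07,0
Jul,13,fish_eggs,0.08,0.07,0
Jul,13,copepods,15.23,9.95,0
Jul,13,chaetognaths,0,0,0
Jul,13,appendicularians,0,0,0
Sep,13,siphonophores,0.08,0.0,0
Sep,13,pteropods,0,0,0
Sep,13,ostracods,0,0,0
Sep,13,furcilia,0,0,0
Sep,13,fish_larvae,0,0,0
Sep,13,fish_eggs,0,0,0
Sep,13,copepods,1.38,0.46,0
Sep,13,chaetognaths,0,0,0
Sep,13,appendicularians,0,0,0
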
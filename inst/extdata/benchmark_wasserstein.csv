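attribute,Proposed,GM,SDV,CTGAN
Pregnancies,0.077049,0.050503,0.210039,0.090343
Glucose,0.139552,0.029401,0.022376,0.211049
BloodPressure,0.119209,0.077486,0.054027,0.135793
SkinThickness,0.166620,0.082580,0.192674,0.063013
Insulin,0.047145,0.381628,0.444365,0.161786
BMI,0.155688,0.026149,0.053898,0.111652
DiabetesPedigreeFunction,0.176867,0.051625,0.125081,0.057591
Age,0.086909,0.022935,0.385533,0.031314
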
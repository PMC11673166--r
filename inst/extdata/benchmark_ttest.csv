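attribute,Proposed,GM,SDV,CTGAN
Pregnancies,0.0000,0.0271,0.4539,0.0000
Glucose,0.0000,0.9834,0.6115,0.0000
BloodPressure,0.0000,0.3075,0.8030,0.1696
SkinThickness,0.1127,0.8747,0.9245,0.6030
Insulin,0.0000,0.8664,0.6294,0.0000
BMI,0.0019,0.7159,0.8157,0.0000
DiabetesPedigreeFunction,0.0009,0.8929,0.1311,0.0000
Age,0.3811,0.3766,0.6342,0.0010
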
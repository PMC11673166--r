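method,model,accuracy,precision,recall,f1
Real,knn,0.6623,0.6388,0.6623,0.6256
GM,knn,0.6234,0.5839,0.6234,0.5824
SDV,knn,0.5065,0.5511,0.5065,0.5167
CTGAN,knn,0.5584,0.6384,0.5584,0.5627
Proposed,knn,0.6494,0.6304,0.6494,0.6326
Real,decision_tree,0.7078,0.709,0.7078,0.7084
GM,decision_tree,0.6818,0.6739,0.6818,0.6764
SDV,decision_tree,0.5649,0.6167,0.5649,0.5735
CTGAN,decision_tree,0.4545,0.4954,0.4545,0.4659
Proposed,decision_tree,0.6883,0.6859,0.6883,0.6873
Real,random_forest,0.7532,0.7554,0.7532,0.7542
GM,random_forest,0.7468,0.7426,0.7468,0.7438
SDV,random_forest,0.6494,0.7648,0.6494,0.6494
CTGAN,random_forest,0.3312,0.388,0.3312,0.2812
Proposed,random_forest,0.7078,0.6966,0.7078,0.6926
Real,mlp,0.6688,0.648,0.6688,0.6307
GM,mlp,0.5649,0.6122,0.5649,0.5738
SDV,mlp,0.3636,0.7712,0.3636,0.2017
CTGAN,mlp,0.4545,0.5942,0.4545,0.4246
Proposed,mlp,0.6558,0.6311,0.6558,0.5831
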
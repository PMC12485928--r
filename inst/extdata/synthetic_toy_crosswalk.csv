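label,label_l3,label_l2,label_l1,cl_label,cl_id,match_level
endothelial cell,endothelial cell,endothelial cell,endothelial,endothelial cell,CL:0000115,exactMatch
t cell,t cell,t cell,immune,T cell,CL:0000084,exactMatch
cd8+ t cell,cd8-positive t cell,t cell,immune,"CD8-positive, alpha-beta T cell",CL:0000625,narrowMatch
b cell,b cell,b cell,immune,B cell,CL:0000236,exactMatch
macrophage,macrophage,macrophage,immune,macrophage,CL:0000235,exactMatch
epithelial cell,epithelial cell,epithelial cell,epithelial,epithelial cell,CL:0000066,exactMatch
fibroblast,fibroblast,fibroblast,mesenchymal,fibroblast,CL:0000057,exactMatch
smooth muscle cell,smooth muscle cell,muscle cell,mesenchymal,smooth muscle cell,CL:0000192,exactMatch
neuron,neuron,neuron,neural,neuron,CL:0000540,exactMatch
unknown,unknown,unknown,unknown,cell,CL:0000000,narrowMatch
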
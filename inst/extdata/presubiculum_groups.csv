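parcel_id,name,group
LEC,lateral entorhinal cortex,LEC
dMEC,medial entorhinal cortex dorsal zone,dMEC
DG,dentate gyrus,DG
CA1,Cornu Ammonis 1,CA3+CA1
CA2,Cornu Ammonis 2,CA3+CA1
CA3,Cornu Ammonis 3,CA3+CA1
Sub,subiculum,Sub
ParaS,parasubiculum,ParaS
PostS,postsubiculum,PostS
PreS,presubiculum,PreS
Retrohipp,retrohippocampal region,Retrohipp
RSPd,retrosplenial cortex dorsal granular,DV(gr.)RtSpl
RSPv,retrosplenial cortex ventral granular,DV(gr.)RtSpl
RSPagl,retrosplenial cortex lateral agranular,L(ag.)RtSpl
SCm,superior colliculus,MidB
IC,inferior colliculus,MidB
LHA,lateral hypothalamic area,Hyp
MM,medial mammillary nucleus,MM+LZ
LZ,hypothalamic lateral zone,MM+LZ
LM,lateral mammillary nucleus,MBO+LM
MBO,mammillary body,MBO+LM
PMd,dorsal premammillary nucleus,PMdv+TU
PMv,ventral premammillary nucleus,PMdv+TU
TU,tuberal nucleus,PMdv+TU
AMm,anteromedial thalamic nucleus medial,mATN+PT
PT,parataenial nucleus,mATN+PT
LGN,lateral geniculate nucleus,TH+LGN
TH,thalamus other,TH+LGN
AD,anterodorsal thalamic nucleus,LD+AD
LD,lateral dorsal thalamic nucleus,LD+AD
IAD,interanterodorsal thalamic nucleus,IAD+IAM
IAM,interanteromedial thalamic nucleus,IAD+IAM
AV,anteroventral thalamic nucleus,dvATN+MGN
AMd,anteromedial thalamic nucleus dorsal,dvATN+MGN
MGN,medial geniculate nucleus,dvATN+MGN
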
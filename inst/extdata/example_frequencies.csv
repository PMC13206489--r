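"locus","allele","frequency","n_typed"
"LOC01","6",0.00823286252900803,1000
"LOC01","7",0.132428473443469,1000
"LOC01","8",0.44201176765236,1000
"LOC01","9",0.294432959608369,1000
"LOC01","10",0.0800983686952627,1000
"LOC01","11",0.0427955680715319,1000
"LOC02","6.3",0.0290043407235171,1000
"LOC02","7",0.170088918715122,1000
"LOC02","8",0.308294304174366,1000
"LOC02","9",0.267524559431606,1000
"LOC02","10",0.0383955461566871,1000
"LOC02","11",0.11769022436549,1000
"LOC02","12",0.0384289875771119,1000
"LOC02","13",0.0278602751247259,1000
"LOC02","14",0.00271284373137311,1000
"LOC03","6",0.0775476868183077,1000
"LOC03","7",0.0435163921808216,1000
"LOC03","8",0.118216934497271,1000
"LOC03","9",0.211592786896585,1000
"LOC03","10",0.057926974101653,1000
"LOC03","11.3",0.148576226074729,1000
"LOC03","12",0.0666007159961983,1000
"LOC03","13",0.0911751941324297,1000
"LOC03","14",0.0587731017444795,1000
"LOC03","15",0.0876507208962897,1000
"LOC03","16",0.0213423343841006,1000
"LOC03","17.3",0.0170809322771352,1000
"LOC04","6.3",0.0259877066360448,1000
"LOC04","7",0.0292475637437902,1000
"LOC04","8",0.0861893936125902,1000
"LOC04","9",0.124474641718965,1000
"LOC04","10",0.031821943136936,1000
"LOC04","11",0.0553541546850864,1000
"LOC04","12",0.094196893984998,1000
"LOC04","13",0.103770243812743,1000
"LOC04","14.3",0.113896874122559,1000
"LOC04","15",0.0863679584984482,1000
"LOC04","16",0.114165671823994,1000
"LOC04","17",0.0273027662155891,1000
"LOC04","18.3",0.0689531637452592,1000
"LOC04","19",0.0382710242629972,1000
"LOC05","6",0.0524218375696145,1000
"LOC05","7",0.0274368833343647,1000
"LOC05","8",0.0133379276257575,1000
"LOC05","9",0.062164762791149,1000
"LOC05","10.3",0.0650071232771156,1000
"LOC05","11",0.0200352394671862,1000
"LOC05","12",0.112492170038005,1000
"LOC05","13",0.0375440770803776,1000
"LOC05","14",0.083265024730572,1000
"LOC05","15",0.0758134572964537,1000
"LOC05","16",0.0796260189363214,1000
"LOC05","17",0.0593572418765652,1000
"LOC05","18",0.132074338304545,1000
"LOC05","19",0.0830377140370177,1000
"LOC05","20",0.031032799850902,1000
"LOC05","21.3",0.0452092137245991,1000
"LOC05","22",0.0201441700594528,1000
"LOC06","6.3",0.0149028211544335,1000
"LOC06","7",0.0244075825486971,1000
"LOC06","8",0.0252235573510465,1000
"LOC06","9",0.0564217109343316,1000
"LOC06","10",0.0577606322154109,1000
"LOC06","11",0.0169003661583236,1000
"LOC06","12",0.0282044005209165,1000
"LOC06","13",0.029349127566156,1000
"LOC06","14",0.0537790562152774,1000
"LOC06","15",0.0985708298397493,1000
"LOC06","16.3",0.167163274703726,1000
"LOC06","17",0.0679455918448692,1000
"LOC06","18",0.0889967244163963,1000
"LOC06","19",0.0536566622245388,1000
"LOC06","20",0.0251351744645715,1000
"LOC06","21",0.0527505227084545,1000
"LOC06","22",0.0360340618146741,1000
"LOC06","23",0.0635553709728957,1000
"LOC06","24",0.0237668772711012,1000
"LOC06","25",0.0154756550744302,1000
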
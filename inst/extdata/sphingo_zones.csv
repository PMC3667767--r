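index,name,zone,in_core,approx
X57,serine palmitoyltransferase,red,TRUE,FALSE
X27,3-KDHS reductase,red,TRUE,FALSE
X34,ceramide synthase,blue,TRUE,FALSE
X36,sphingoid base kinase,blue,TRUE,FALSE
X41,sphingoid-1-phosphate phosphatase,blue,TRUE,FALSE
X54,4-hydroxylase,blue,TRUE,FALSE
X50,sphingosine-phosphate lyase,blue,TRUE,FALSE
X43,GPI remodelase,blue,TRUE,FALSE
X59,ELO1p very long chain fatty acid elongase,blue,FALSE,FALSE
X29,dihydroceramide alkaline ceramidase,blue,TRUE,FALSE
X53,phytoceramide alkaline ceramidase,blue,TRUE,FALSE
X33,IPC synthase,green,TRUE,FALSE
X35,MIPC synthase,green,TRUE,FALSE
X55,M(IP)2C synthase,green,TRUE,FALSE
X51,IPCase (ISC1),green,TRUE,FALSE
X52,fatty acid synthase,yellow,FALSE,FALSE
X60,acetyl-CoA carboxylase,yellow,FALSE,FALSE
X63,malonyl-CoA synthase,yellow,FALSE,FALSE
X26,phospholipid-pathway enzyme,tan,FALSE,TRUE
X31,phospholipid-pathway enzyme,tan,FALSE,TRUE
X32,phospholipid-pathway enzyme,tan,FALSE,TRUE
X38,phospholipid-pathway enzyme,tan,FALSE,TRUE
X39,phospholipid-pathway enzyme,tan,FALSE,TRUE
X40,phospholipid-pathway enzyme,tan,FALSE,TRUE
X42,phospholipid-pathway enzyme,tan,FALSE,TRUE
X44,phospholipid-pathway enzyme,tan,FALSE,TRUE
X45,serine-metabolism enzyme,pink,FALSE,TRUE
X46,serine-metabolism enzyme,pink,FALSE,TRUE
X49,serine-metabolism enzyme,pink,FALSE,TRUE
X56,serine-metabolism enzyme,pink,FALSE,TRUE
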
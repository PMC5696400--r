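region1,region2,p_f1_12loci,sig_f1_12loci,p_ci_12loci,sig_ci_12loci
Florida_R2,South_Carolina_R6,<.00001,TRUE,<.00001,TRUE
Florida_R2,Georgia_R5,.00076,TRUE,<.00001,TRUE
Florida_R2,Virginia_R8,.07818,FALSE,.01572,FALSE
Florida_R2,Virginia_R9,.00029,TRUE,<.00001,TRUE
South_Carolina_R6,Georgia_R5,1,FALSE,.87045,FALSE
South_Carolina_R6,Virginia_R8,.00035,TRUE,<.00001,TRUE
South_Carolina_R6,Virginia_R9,.01493,FALSE,.00002,TRUE
Georgia_R5,Virginia_R8,.03024,FALSE,.00009,TRUE
Georgia_R5,Virginia_R9,.21913,FALSE,.34276,FALSE
Virginia_R8,Virginia_R9,.57349,FALSE,.05069,FALSE
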
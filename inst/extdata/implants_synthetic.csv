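id,brand,shape,base_diameter_mm,projection_mm,volume_cc
RND-180-M,SynthImplant,round,105,35,180
RND-200-M,SynthImplant,round,110,38,200
RND-220-M,SynthImplant,round,112,40,220
RND-250-F,SynthImplant,round,115,44,250
RND-280-F,SynthImplant,round,118,47,280
RND-300-F,SynthImplant,round,120,50,300
RND-150-L,SynthImplant,round,100,33,150
RND-325-X,SynthImplant,round,122,53,325
ANA-200-M,SynthContour,anatomical,110,40,200
ANA-240-M,SynthContour,anatomical,114,44,240
ANA-270-F,SynthContour,anatomical,118,47,270
ANA-310-F,SynthContour,anatomical,122,51,310
ANA-160-L,SynthContour,anatomical,104,36,160
ANA-350-X,SynthContour,anatomical,126,55,350
RND-195-H,SynthProfile,round,98,45,195
RND-230-H,SynthProfile,round,102,49,230
ANA-205-H,SynthProfile,anatomical,100,47,205
RND-175-S,SynthProfile,round,108,30,175
ANA-290-S,SynthContour,anatomical,124,42,290
RND-265-S,SynthImplant,round,121,39,265
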
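"species_code","c1","c2","cp","swc_min","swc_max","psi","gdd_min","gdd_max","shade_tolerance_class"
"sp01",2.09950614690781,1.08769343339428,0.0819682100508362,0.0574898413615301,0.956224326917436,0.72023741255538,944.671018719673,3067.34363228083,1
"sp02",1.892526858659,2.16786630861741,0.0743715322203934,0.0646995528368279,0.9814441993949,0.825677651340534,774.203417003155,3146.6693392396,2
"sp03",1.47209001304395,2.91343032385744,0.0797178209666163,0.0569931892678142,0.759906999650411,0.250216199554481,603.232890069485,2425.16275256872,3
"sp04",1.27758948309161,3.76294183891062,0.0616580082755536,0.142318583559245,0.958193208731245,0.338420071315314,263.490689098835,1572.18635708094,4
"sp05",0.986990069132298,4.82937213628739,0.0577496468834579,0.0485015340382233,0.844690326543059,0.21937211156942,933.909958600998,3279.81534004211,5
"sp06",2.10214688314497,1.20892531983852,0.0725066982582211,0.0739938071346842,0.822191682644188,0.311326634089228,427.097654044628,2955.9464392066,1
"sp07",1.89586645821761,2.14280649927706,0.0709580994024873,0.237591694225557,0.973646954633296,0.733477932338126,522.263372540474,2686.48138523102,2
"sp08",1.51676963196974,3.04810123176165,0.0574691121466458,0.19805965811247,0.78790735558141,0.4258186152641,997.121865153313,2840.09140789509,3
"sp09",1.40208836201299,4.10954500875827,0.0418410359695554,0.00339229591190815,0.78711444477085,0.480906676073645,1142.90270030499,3512.06344038248,4
"sp10",1.00555247375742,4.83576284020394,0.0320901329722256,0.177018007612787,0.75985352054704,0.345434098198867,444.658481776714,2710.66056847572,5
"sp11",2.17055545851588,1.14516235575527,0.0668942783866078,0.125961126876064,0.841235950880218,0.575753275230306,298.88544678688,1600.79236268997,1
"sp12",1.74547493089503,2.16960723731387,0.0545093259587884,0.0469548019464128,0.764390704629477,0.48667020038637,1310.77980130911,2925.09091436863,2
"sp13",1.60672852906119,3.12085239761285,0.0725497667212039,0.121550661977381,0.976504066435155,0.693362974176128,832.754786014557,2356.69696122408,3
"sp14",1.27601214153133,3.5989961429067,0.0596048357337713,0.00990791217191145,0.785732147225644,0.311629435596266,816.188651323318,3021.16721451283,4
"sp15",0.94204159937799,4.95229709311575,0.0640862622670829,0.191733102139551,0.787699564592913,0.470717779946192,975.943806171417,2675.24402976036,5
"sp16",2.09201135493815,1.11980180945173,0.0704918734822422,0.14430876262486,0.851240075717214,0.631838574720594,938.269289135933,3171.83033913374,1
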
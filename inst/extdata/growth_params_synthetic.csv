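"species_code","g_growth","d_max","h_max","age_max","shade_tolerance_class","gdd_min","gdd_max","swc_min","swc_max","psi","biomass_a","biomass_b","recruit_rate"
"sp01",260.138142738491,56.5682828146964,2775.72461711243,81.0385001674295,1,944.671018719673,3067.34363228083,0.0574898413615301,0.956224326917436,0.72023741255538,0.119230201421306,2.33473080797121,1.94509986590128
"sp02",233.690953454934,43.2864969596267,3103.39405396953,138.589624291752,2,774.203417003155,3146.6693392396,0.0646995528368279,0.9814441993949,0.825677651340534,0.0997792464215308,2.53005741657689,0.96866465092171
"sp03",171.93150288891,61.6111882030964,2684.65663893148,211.184201794211,3,603.232890069485,2425.16275256872,0.0569931892678142,0.759906999650411,0.250216199554481,0.0594063747441396,2.50900418236852,1.89077524899039
"sp04",156.680426100036,45.8321669325233,2738.4102310054,275.392064345069,4,263.490689098835,1572.18635708094,0.142318583559245,0.958193208731245,0.338420071315314,0.0586442432599142,2.24163007037714,1.79960748949088
"sp05",115.264125745744,54.7774492017925,2061.47990887985,366.439654001035,5,933.909958600998,3279.81534004211,0.0485015340382233,0.844690326543059,0.21937211156942,0.0924449412617832,2.43426168644801,0.916392746032216
"sp06",258.616706339642,55.6420458760113,2957.13107185438,81.8756718561053,1,427.097654044628,2955.9464392066,0.0739938071346842,0.822191682644188,0.311326634089228,0.142818373511545,2.5526982774958,1.66133951209486
"sp07",236.092488218565,56.950749270618,2316.4563097991,155.473371438216,2,522.263372540474,2686.48138523102,0.237591694225557,0.973646954633296,0.733477932338126,0.137397724878974,2.28447123244405,1.99054932803847
"sp08",192.738958056551,50.9563039708883,2430.64416386187,208.973770317156,3,997.121865153313,2840.09140789509,0.19805965811247,0.78790735558141,0.4258186152641,0.131864061090164,2.39580905074254,1.78396158316173
"sp09",162.230794397881,62.4521069042385,2540.68834278733,297.806817772798,4,1142.90270030499,3512.06344038248,0.00339229591190815,0.78711444477085,0.480906676073645,0.0553514946252108,2.50098993619904,1.67280490580015
"sp10",116.268862210214,63.425383605063,2111.7424653843,353.554455197416,5,444.658481776714,2710.66056847572,0.177018007612787,0.75985352054704,0.345434098198867,0.0578550525708124,2.39780677799135,0.70140000898391
"sp11",234.819916878827,62.9060274828225,3072.54040334374,83.2877579107881,1,298.88544678688,1600.79236268997,0.125961126876064,0.841235950880218,0.575753275230306,0.0701710374094546,2.28272420363501,1.89284894964658
"sp12",215.375322480686,46.3848937768489,2363.01784170792,148.338111004327,2,1310.77980130911,2925.09091436863,0.0469548019464128,0.764390704629477,0.48667020038637,0.125008792127483,2.55582598932087,1.22917396540288
"sp13",195.505750639364,73.9215533901006,2678.17847970873,210.75691169221,3,832.754786014557,2356.69696122408,0.121550661977381,0.976504066435155,0.693362974176128,0.134316863236018,2.45180701641366,0.623261370696127
"sp14",153.258851691382,41.6045290976763,2664.22276264057,296.563175579067,4,816.188651323318,3021.16721451283,0.00990791217191145,0.785732147225644,0.311629435596266,0.135502333100885,2.43005977869034,1.53085037425626
"sp15",109.197667865083,68.48095132038,2974.77616602555,357.441414539702,5,975.943806171417,2675.24402976036,0.191733102139551,0.787699564592913,0.470717779946192,0.09696015692316,2.52668124390766,1.41804535442498
"sp16",238.258512205444,57.6597241871059,2327.23486004397,83.7380722276866,1,938.269289135933,3171.83033913374,0.14430876262486,0.851240075717214,0.631838574720594,0.145506604877301,2.30355817889795,1.52164489496499
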
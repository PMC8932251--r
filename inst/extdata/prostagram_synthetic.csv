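id,mri,ultrasound,psa,verified,disease
P001,1,1,1,1,1
P002,1,1,1,1,1
P003,1,1,1,1,1
P004,1,1,1,1,0
P005,1,1,0,1,1
P006,1,1,0,1,1
P007,1,1,0,1,1
P008,1,1,0,1,1
P009,1,1,0,1,1
P010,1,1,0,1,0
P011,1,1,0,1,0
P012,1,1,0,1,0
P013,1,1,0,1,0
P014,1,1,0,1,0
P015,1,1,0,1,0
P016,1,1,0,1,0
P017,1,1,0,1,0
P018,1,1,0,1,0
P019,1,1,0,1,0
P020,1,1,0,1,0
P021,1,1,0,1,0
P022,1,1,0,1,0
P023,1,1,0,1,0
P024,1,1,0,1,0
P025,1,1,0,1,0
P026,1,1,0,1,0
P027,1,1,0,1,0
P028,1,1,0,1,0
P029,1,1,0,1,0
P030,1,1,0,1,0
P031,1,1,0,1,0
P032,1,1,0,1,0
P033,1,0,1,1,1
P034,1,0,1,1,0
P035,1,0,1,1,0
P036,1,0,1,1,0
P037,1,0,0,1,1
P038,1,0,0,1,1
P039,1,0,0,1,1
P040,1,0,0,1,1
P041,1,0,0,1,1
P042,1,0,0,1,0
P043,1,0,0,1,0
P044,1,0,0,1,0
P045,1,0,0,1,0
P046,1,0,0,1,0
P047,1,0,0,1,0
P048,1,0,0,1,0
P049,1,0,0,1,0
P050,1,0,0,1,0
P051,1,0,0,1,0
P052,1,0,0,1,0
P053,1,0,0,1,0
P054,1,0,0,1,0
P055,1,0,0,1,0
P056,1,0,0,1,0
P057,1,0,0,1,0
P058,1,0,0,1,0
P059,1,0,0,1,0
P060,1,0,0,1,0
P061,1,0,0,1,0
P062,1,0,0,1,0
P063,1,0,0,1,0
P064,1,0,0,1,0
P065,1,0,0,1,0
P066,1,0,0,1,0
P067,1,0,0,1,0
P068,1,0,0,1,0
P069,1,0,0,1,0
P070,1,0,0,1,0
P071,1,0,0,1,0
P072,1,0,0,1,0
P073,1,0,0,1,0
P074,1,0,0,1,0
P075,1,0,0,1,0
P076,1,0,0,1,0
P077,1,0,0,1,0
P078,1,0,0,1,0
P079,1,0,0,1,0
P080,1,0,0,1,0
P081,1,0,0,1,0
P082,1,0,0,1,0
P083,1,0,0,1,0
P084,1,0,0,1,0
P085,1,0,0,1,0
P086,1,0,0,1,0
P087,1,0,0,1,0
P088,1,0,0,1,0
P089,0,1,1,1,1
P090,0,1,1,1,0
P091,0,1,1,1,0
P092,0,1,0,1,0
P093,0,1,0,1,0
P094,0,1,0,1,0
P095,0,1,0,1,0
P096,0,1,0,1,0
P097,0,1,0,1,0
P098,0,1,0,1,0
P099,0,1,0,1,0
P100,0,1,0,1,0
P101,0,1,0,1,0
P102,0,1,0,1,0
P103,0,1,0,1,0
P104,0,1,0,1,0
P105,0,1,0,1,0
P106,0,1,0,1,0
P107,0,1,0,1,0
P108,0,1,0,1,0
P109,0,1,0,1,0
P110,0,1,0,1,0
P111,0,1,0,1,0
P112,0,1,0,1,0
P113,0,1,0,1,0
P114,0,1,0,1,0
P115,0,1,0,1,0
P116,0,1,0,1,0
P117,0,1,0,1,0
P118,0,1,0,1,0
P119,0,1,0,1,0
P120,0,1,0,1,0
P121,0,1,0,1,0
P122,0,1,0,1,0
P123,0,1,0,1,0
P124,0,1,0,1,0
P125,0,1,0,1,0
P126,0,1,0,1,0
P127,0,1,0,1,0
P128,0,1,0,1,0
P129,0,1,0,1,0
P130,0,1,0,1,0
P131,0,1,0,1,0
P132,0,1,0,1,0
P133,0,1,0,1,0
P134,0,1,0,1,0
P135,0,1,0,1,0
P136,0,1,0,1,0
P137,0,1,0,1,0
P138,0,1,0,1,0
P139,0,1,0,1,0
P140,0,1,0,1,0
P141,0,1,0,1,0
P142,0,0,1,1,1
P143,0,0,1,1,0
P144,0,0,1,1,0
P145,0,0,1,1,0
P146,0,0,1,1,0
P147,0,0,1,1,0
P148,0,0,1,1,0
P149,0,0,1,1,0
P150,0,0,1,1,0
P151,0,0,1,1,0
P152,0,0,1,1,0
P153,0,0,1,1,0
P154,0,0,1,1,0
P155,0,0,1,1,0
P156,0,0,1,1,0
P157,0,0,1,1,0
P158,0,0,1,1,0
P159,0,0,1,1,0
P160,0,0,1,1,0
P161,0,0,1,1,0
P162,0,0,1,1,0
P163,0,0,1,1,0
P164,0,0,1,1,0
P165,0,0,1,1,0
P166,0,0,0,1,0
P167,1,1,0,0,
P168,1,1,0,0,
P169,1,1,0,0,
P170,1,0,1,0,
P171,1,0,0,0,
P172,1,0,0,0,
P173,1,0,0,0,
P174,1,0,0,0,
P175,1,0,0,0,
P176,0,1,1,0,
P177,0,1,1,0,
P178,0,1,0,0,
P179,0,1,0,0,
P180,0,1,0,0,
P181,0,1,0,0,
P182,0,1,0,0,
P183,0,0,1,0,
P184,0,0,0,0,
P185,0,0,0,0,
P186,0,0,0,0,
P187,0,0,0,0,
P188,0,0,0,0,
P189,0,0,0,0,
P190,0,0,0,0,
P191,0,0,0,0,
P192,0,0,0,0,
P193,0,0,0,0,
P194,0,0,0,0,
P195,0,0,0,0,
P196,0,0,0,0,
P197,0,0,0,0,
P198,0,0,0,0,
P199,0,0,0,0,
P200,0,0,0,0,
P201,0,0,0,0,
P202,0,0,0,0,
P203,0,0,0,0,
P204,0,0,0,0,
P205,0,0,0,0,
P206,0,0,0,0,
P207,0,0,0,0,
P208,0,0,0,0,
P209,0,0,0,0,
P210,0,0,0,0,
P211,0,0,0,0,
P212,0,0,0,0,
P213,0,0,0,0,
P214,0,0,0,0,
P215,0,0,0,0,
P216,0,0,0,0,
P217,0,0,0,0,
P218,0,0,0,0,
P219,0,0,0,0,
P220,0,0,0,0,
P221,0,0,0,0,
P222,0,0,0,0,
P223,0,0,0,0,
P224,0,0,0,0,
P225,0,0,0,0,
P226,0,0,0,0,
P227,0,0,0,0,
P228,0,0,0,0,
P229,0,0,0,0,
P230,0,0,0,0,
P231,0,0,0,0,
P232,0,0,0,0,
P233,0,0,0,0,
P234,0,0,0,0,
P235,0,0,0,0,
P236,0,0,0,0,
P237,0,0,0,0,
P238,0,0,0,0,
P239,0,0,0,0,
P240,0,0,0,0,
P241,0,0,0,0,
P242,0,0,0,0,
P243,0,0,0,0,
P244,0,0,0,0,
P245,0,0,0,0,
P246,0,0,0,0,
P247,0,0,0,0,
P248,0,0,0,0,
P249,0,0,0,0,
P250,0,0,0,0,
P251,0,0,0,0,
P252,0,0,0,0,
P253,0,0,0,0,
P254,0,0,0,0,
P255,0,0,0,0,
P256,0,0,0,0,
P257,0,0,0,0,
P258,0,0,0,0,
P259,0,0,0,0,
P260,0,0,0,0,
P261,0,0,0,0,
P262,0,0,0,0,
P263,0,0,0,0,
P264,0,0,0,0,
P265,0,0,0,0,
P266,0,0,0,0,
P267,0,0,0,0,
P268,0,0,0,0,
P269,0,0,0,0,
P270,0,0,0,0,
P271,0,0,0,0,
P272,0,0,0,0,
P273,0,0,0,0,
P274,0,0,0,0,
P275,0,0,0,0,
P276,0,0,0,0,
P277,0,0,0,0,
P278,0,0,0,0,
P279,0,0,0,0,
P280,0,0,0,0,
P281,0,0,0,0,
P282,0,0,0,0,
P283,0,0,0,0,
P284,0,0,0,0,
P285,0,0,0,0,
P286,0,0,0,0,
P287,0,0,0,0,
P288,0,0,0,0,
P289,0,0,0,0,
P290,0,0,0,0,
P291,0,0,0,0,
P292,0,0,0,0,
P293,0,0,0,0,
P294,0,0,0,0,
P295,0,0,0,0,
P296,0,0,0,0,
P297,0,0,0,0,
P298,0,0,0,0,
P299,0,0,0,0,
P300,0,0,0,0,
P301,0,0,0,0,
P302,0,0,0,0,
P303,0,0,0,0,
P304,0,0,0,0,
P305,0,0,0,0,
P306,0,0,0,0,
P307,0,0,0,0,
P308,0,0,0,0,
P309,0,0,0,0,
P310,0,0,0,0,
P311,0,0,0,0,
P312,0,0,0,0,
P313,0,0,0,0,
P314,0,0,0,0,
P315,0,0,0,0,
P316,0,0,0,0,
P317,0,0,0,0,
P318,0,0,0,0,
P319,0,0,0,0,
P320,0,0,0,0,
P321,0,0,0,0,
P322,0,0,0,0,
P323,0,0,0,0,
P324,0,0,0,0,
P325,0,0,0,0,
P326,0,0,0,0,
P327,0,0,0,0,
P328,0,0,0,0,
P329,0,0,0,0,
P330,0,0,0,0,
P331,0,0,0,0,
P332,0,0,0,0,
P333,0,0,0,0,
P334,0,0,0,0,
P335,0,0,0,0,
P336,0,0,0,0,
P337,0,0,0,0,
P338,0,0,0,0,
P339,0,0,0,0,
P340,0,0,0,0,
P341,0,0,0,0,
P342,0,0,0,0,
P343,0,0,0,0,
P344,0,0,0,0,
P345,0,0,0,0,
P346,0,0,0,0,
P347,0,0,0,0,
P348,0,0,0,0,
P349,0,0,0,0,
P350,0,0,0,0,
P351,0,0,0,0,
P352,0,0,0,0,
P353,0,0,0,0,
P354,0,0,0,0,
P355,0,0,0,0,
P356,0,0,0,0,
P357,0,0,0,0,
P358,0,0,0,0,
P359,0,0,0,0,
P360,0,0,0,0,
P361,0,0,0,0,
P362,0,0,0,0,
P363,0,0,0,0,
P364,0,0,0,0,
P365,0,0,0,0,
P366,0,0,0,0,
P367,0,0,0,0,
P368,0,0,0,0,
P369,0,0,0,0,
P370,0,0,0,0,
P371,0,0,0,0,
P372,0,0,0,0,
P373,0,0,0,0,
P374,0,0,0,0,
P375,0,0,0,0,
P376,0,0,0,0,
P377,0,0,0,0,
P378,0,0,0,0,
P379,0,0,0,0,
P380,0,0,0,0,
P381,0,0,0,0,
P382,0,0,0,0,
P383,0,0,0,0,
P384,0,0,0,0,
P385,0,0,0,0,
P386,0,0,0,0,
P387,0,0,0,0,
P388,0,0,0,0,
P389,0,0,0,0,
P390,0,0,0,0,
P391,0,0,0,0,
P392,0,0,0,0,
P393,0,0,0,0,
P394,0,0,0,0,
P395,0,0,0,0,
P396,0,0,0,0,
P397,0,0,0,0,
P398,0,0,0,0,
P399,0,0,0,0,
P400,0,0,0,0,
P401,0,0,0,0,
P402,0,0,0,0,
P403,0,0,0,0,
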
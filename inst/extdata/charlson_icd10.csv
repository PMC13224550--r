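prefix,category,weight,group
I21,myocardial_infarction,1,cardiovascular
I22,myocardial_infarction,1,cardiovascular
I252,myocardial_infarction,1,cardiovascular
I099,congestive_heart_failure,1,cardiovascular
I110,congestive_heart_failure,1,cardiovascular
I130,congestive_heart_failure,1,cardiovascular
I132,congestive_heart_failure,1,cardiovascular
I255,congestive_heart_failure,1,cardiovascular
I420,congestive_heart_failure,1,cardiovascular
I425,congestive_heart_failure,1,cardiovascular
I426,congestive_heart_failure,1,cardiovascular
I427,congestive_heart_failure,1,cardiovascular
I428,congestive_heart_failure,1,cardiovascular
I429,congestive_heart_failure,1,cardiovascular
I43,congestive_heart_failure,1,cardiovascular
I50,congestive_heart_failure,1,cardiovascular
P290,congestive_heart_failure,1,cardiovascular
I70,peripheral_vascular,1,cardiovascular
I71,peripheral_vascular,1,cardiovascular
I731,peripheral_vascular,1,cardiovascular
I738,peripheral_vascular,1,cardiovascular
I739,peripheral_vascular,1,cardiovascular
I771,peripheral_vascular,1,cardiovascular
I790,peripheral_vascular,1,cardiovascular
I792,peripheral_vascular,1,cardiovascular
K551,peripheral_vascular,1,cardiovascular
K558,peripheral_vascular,1,cardiovascular
K559,peripheral_vascular,1,cardiovascular
Z958,peripheral_vascular,1,cardiovascular
Z959,peripheral_vascular,1,cardiovascular
G45,cerebrovascular,1,cardiovascular
G46,cerebrovascular,1,cardiovascular
H340,cerebrovascular,1,cardiovascular
I60,cerebrovascular,1,cardiovascular
I61,cerebrovascular,1,cardiovascular
I62,cerebrovascular,1,cardiovascular
I63,cerebrovascular,1,cardiovascular
I64,cerebrovascular,1,cardiovascular
I65,cerebrovascular,1,cardiovascular
I66,cerebrovascular,1,cardiovascular
I67,cerebrovascular,1,cardiovascular
I68,cerebrovascular,1,cardiovascular
I69,cerebrovascular,1,cardiovascular
F00,dementia,1,
F01,dementia,1,
F02,dementia,1,
F03,dementia,1,
F051,dementia,1,
G30,dementia,1,
G311,dementia,1,
J40,chronic_pulmonary,1,pulmonary
J41,chronic_pulmonary,1,pulmonary
J42,chronic_pulmonary,1,pulmonary
J43,chronic_pulmonary,1,pulmonary
J44,chronic_pulmonary,1,pulmonary
J45,chronic_pulmonary,1,pulmonary
J46,chronic_pulmonary,1,pulmonary
J47,chronic_pulmonary,1,pulmonary
J60,chronic_pulmonary,1,pulmonary
J61,chronic_pulmonary,1,pulmonary
J62,chronic_pulmonary,1,pulmonary
J63,chronic_pulmonary,1,pulmonary
J64,chronic_pulmonary,1,pulmonary
J65,chronic_pulmonary,1,pulmonary
J66,chronic_pulmonary,1,pulmonary
J67,chronic_pulmonary,1,pulmonary
J684,chronic_pulmonary,1,pulmonary
J701,chronic_pulmonary,1,pulmonary
J703,chronic_pulmonary,1,pulmonary
M05,rheumatic,1,
M06,rheumatic,1,
M315,rheumatic,1,
M32,rheumatic,1,
M33,rheumatic,1,
M34,rheumatic,1,
M351,rheumatic,1,
M353,rheumatic,1,
M360,rheumatic,1,
K25,peptic_ulcer,1,
K26,peptic_ulcer,1,
K27,peptic_ulcer,1,
K28,peptic_ulcer,1,
B18,mild_liver,1,liver
K700,mild_liver,1,liver
K701,mild_liver,1,liver
K702,mild_liver,1,liver
K703,mild_liver,1,liver
K709,mild_liver,1,liver
K713,mild_liver,1,liver
K714,mild_liver,1,liver
K715,mild_liver,1,liver
K717,mild_liver,1,liver
K73,mild_liver,1,liver
K74,mild_liver,1,liver
K760,mild_liver,1,liver
K762,mild_liver,1,liver
K763,mild_liver,1,liver
K764,mild_liver,1,liver
K768,mild_liver,1,liver
K769,mild_liver,1,liver
Z944,mild_liver,1,liver
E100,diabetes,1,
E101,diabetes,1,
E106,diabetes,1,
E108,diabetes,1,
E109,diabetes,1,
E110,diabetes,1,
E111,diabetes,1,
E116,diabetes,1,
E118,diabetes,1,
E119,diabetes,1,
E102,diabetes_complicated,2,
E103,diabetes_complicated,2,
E104,diabetes_complicated,2,
E105,diabetes_complicated,2,
E107,diabetes_complicated,2,
E112,diabetes_complicated,2,
E113,diabetes_complicated,2,
E114,diabetes_complicated,2,
E115,diabetes_complicated,2,
E117,diabetes_complicated,2,
G041,hemiplegia,2,
G114,hemiplegia,2,
G801,hemiplegia,2,
G802,hemiplegia,2,
G81,hemiplegia,2,
G82,hemiplegia,2,
G830,hemiplegia,2,
G831,hemiplegia,2,
G832,hemiplegia,2,
G833,hemiplegia,2,
G834,hemiplegia,2,
G839,hemiplegia,2,
I120,renal,2,renal
I131,renal,2,renal
N032,renal,2,renal
N033,renal,2,renal
N034,renal,2,renal
N035,renal,2,renal
N036,renal,2,renal
N037,renal,2,renal
N052,renal,2,renal
N053,renal,2,renal
N054,renal,2,renal
N055,renal,2,renal
N056,renal,2,renal
N057,renal,2,renal
N18,renal,2,renal
N19,renal,2,renal
N250,renal,2,renal
Z490,renal,2,renal
Z491,renal,2,renal
Z492,renal,2,renal
Z940,renal,2,renal
Z992,renal,2,renal
C0,malignancy,2,malignancy
C1,malignancy,2,malignancy
C2,malignancy,2,malignancy
C30,malignancy,2,malignancy
C31,malignancy,2,malignancy
C32,malignancy,2,malignancy
C33,malignancy,2,malignancy
C34,malignancy,2,malignancy
C37,malignancy,2,malignancy
C38,malignancy,2,malignancy
C39,malignancy,2,malignancy
C40,malignancy,2,malignancy
C41,malignancy,2,malignancy
C43,malignancy,2,malignancy
C45,malignancy,2,malignancy
C46,malignancy,2,malignancy
C47,malignancy,2,malignancy
C48,malignancy,2,malignancy
C49,malignancy,2,malignancy
C50,malignancy,2,malignancy
C51,malignancy,2,malignancy
C52,malignancy,2,malignancy
C53,malignancy,2,malignancy
C54,malignancy,2,malignancy
C55,malignancy,2,malignancy
C56,malignancy,2,malignancy
C57,malignancy,2,malignancy
C58,malignancy,2,malignancy
C6,malignancy,2,malignancy
C70,malignancy,2,malignancy
C71,malignancy,2,malignancy
C72,malignancy,2,malignancy
C73,malignancy,2,malignancy
C74,malignancy,2,malignancy
C75,malignancy,2,malignancy
C76,malignancy,2,malignancy
C81,malignancy,2,malignancy
C82,malignancy,2,malignancy
C83,malignancy,2,malignancy
C84,malignancy,2,malignancy
C85,malignancy,2,malignancy
C88,malignancy,2,malignancy
C90,malignancy,2,malignancy
C91,malignancy,2,malignancy
C92,malignancy,2,malignancy
C93,malignancy,2,malignancy
C94,malignancy,2,malignancy
C95,malignancy,2,malignancy
C96,malignancy,2,malignancy
C97,malignancy,2,malignancy
I850,severe_liver,3,liver
I859,severe_liver,3,liver
I864,severe_liver,3,liver
I982,severe_liver,3,liver
K704,severe_liver,3,liver
K711,severe_liver,3,liver
K721,severe_liver,3,liver
K729,severe_liver,3,liver
K765,severe_liver,3,liver
K766,severe_liver,3,liver
K767,severe_liver,3,liver
C77,metastatic,6,malignancy
C78,metastatic,6,malignancy
C79,metastatic,6,malignancy
C80,metastatic,6,malignancy
B20,aids,6,
B21,aids,6,
B22,aids,6,
B24,aids,6,
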
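# Synthetic MeSH vocabulary subset (fixture dialect: ui, name, codes joined
# by |). Tree numbers printed in the published category and ICD-10
# correspondence tables are kept verbatim; all other positions are
# synthetic stand-ins arranged to reproduce the worked scoring examples.
D002318	Cardiovascular Diseases	C14
D014652	Vascular Diseases	C14.907
D006973	Hypertension	C14.907.489
D046110	Hypertension, Pregnancy-Induced	C13.703.395|C14.907.489.480
D005261	Female Urogenital Diseases and Pregnancy Complications	C13
D011248	Pregnancy Complications	C13.703
D006331	Heart Diseases	C14.280
D017202	Myocardial Ischemia	C14.280.647|C14.907.585
D009203	Myocardial Infarction	C14.280.647.500|C14.907.585.500
D052776	Urogenital Diseases	C12
D007674	Kidney Diseases	C12.777.419
D003928	Diabetic Nephropathies	C12.777.419.192
D009369	Neoplasms	C04
D007239	Infections	C01
D011154	Population Characteristics	N01
D006262	Health	N01.400
D004778	Environment and Public Health	N06
D011634	Public Health	N06.850|H02.403.720
D006281	Health Occupations	H02
D008511	Medicine	H02.403
D004813	Epidemiology	H02.403.720.500
D007254	Information Science	L01
D009622	Computing Methodologies	L01.224
D000465	Algorithms	L01.224.050
D001185	Artificial Intelligence	L01.224.050.375
D000069550	Machine Learning	L01.224.050.375.530
D009323	Natural Language Processing	L01.224.050.375.580
D016571	Neural Networks, Computer	L01.224.050.375.605
D003142	Communications Media	L01.178
D063990	Informatics	L01.453
D008490	Medical Informatics	L01.453.245
D017216	Telemedicine	L01.453.245.945|L01.224.134
D057286	Electronic Health Records	L01.453.245.300
D003933	Diagnosis	E01
D013812	Therapeutics	E02
D008919	Investigative Techniques	E05
D004864	Equipment and Supplies	E07
D011159	Population Surveillance	N06.850.290|K01.400
D016247	Information Storage and Retrieval	L01.453.453|F02.463|B01.050
D011788	Quality of Life	N01.400.550|K01.752.400.750
D058406	Cardiac Resynchronization Therapy Devices	E07.305.250.300|E07.695.200
D017147	Defibrillators, Implantable	E07.305.250.375|E02.342.500
D058996	Remote Sensing Technology	E05.595.700|E07.670.600
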
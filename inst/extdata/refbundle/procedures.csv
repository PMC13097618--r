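"code","description"
97605,"Negative pressure wound therapy, <= 50 sq cm"
67228,"Treatment of extensive retinopathy, photocoagulation"
92316,"Prescription of optical and physical characteristics of lens"
99213,"Office or other outpatient visit, established patient"
99284,"Emergency department visit, high complexity"
71046,"Radiologic examination, chest; 2 views"
80053,"Comprehensive metabolic panel"
85025,"Blood count; complete (CBC), automated"
93000,"Electrocardiogram, routine ECG with at least 12 leads"
36415,"Collection of venous blood by venipuncture"
90471,"Immunization administration"
97110,"Therapeutic exercises, each 15 minutes"
70450,"CT head or brain without contrast"
72148,"MRI lumbar spine without contrast"
94640,"Pressurized or nonpressurized inhalation treatment"
99291,"Critical care, first 30-74 minutes"
10060,"Incision and drainage of abscess"
12001,"Simple repair of superficial wounds, 2.5 cm or less"
29125,"Application of short arm splint"
51702,"Insertion of temporary indwelling bladder catheter"
J0696,"Injection, ceftriaxone sodium, per 250 mg"
J1885,"Injection, ketorolac tromethamine, per 15 mg"
J2550,"Injection, promethazine HCl, up to 50 mg"
A0429,"Ambulance service, BLS emergency transport"
G0378,"Hospital observation service, per hour"
J3452,"Synthetic procedure stand-in J3452"
60687,"Synthetic procedure stand-in 60687"
83820,"Synthetic procedure stand-in 83820"
J8526,"Synthetic procedure stand-in J8526"
72374,"Synthetic procedure stand-in 72374"
67181,"Synthetic procedure stand-in 67181"
66392,"Synthetic procedure stand-in 66392"
13473,"Synthetic procedure stand-in 13473"
13768,"Synthetic procedure stand-in 13768"
59602,"Synthetic procedure stand-in 59602"
82161,"Synthetic procedure stand-in 82161"
42485,"Synthetic procedure stand-in 42485"
17855,"Synthetic procedure stand-in 17855"
08653,"Synthetic procedure stand-in 08653"
31679,"Synthetic procedure stand-in 31679"
22855,"Synthetic procedure stand-in 22855"
J3335,"Synthetic procedure stand-in J3335"
10199,"Synthetic procedure stand-in 10199"
00171,"Synthetic procedure stand-in 00171"
Q5166,"Synthetic procedure stand-in Q5166"
G1348,"Synthetic procedure stand-in G1348"
05182,"Synthetic procedure stand-in 05182"
75237,"Synthetic procedure stand-in 75237"
69122,"Synthetic procedure stand-in 69122"
18409,"Synthetic procedure stand-in 18409"
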
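{"pmid":"28117445","title":"Worked example one (synthetic record)","year":2017,"language":"eng","country":"United States","publication_types":["Journal Article"],"headings":[{"descriptor_name":"Hypertension","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Population Surveillance","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Information Storage and Retrieval","descriptor_ui":null,"major":true,"qualifiers":[]}]}
{"pmid":"25981148","title":"Worked example two (synthetic record)","year":2015,"language":"eng","country":"United States","publication_types":["Journal Article"],"headings":[{"descriptor_name":"Cardiac Resynchronization Therapy Devices","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Defibrillators, Implantable","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Remote Sensing Technology","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Heart Diseases","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Quality of Life","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Telemedicine","descriptor_ui":null,"major":true,"qualifiers":[]}]}
{"pmid":"90000001","title":"Telehealth for hypertension management (synthetic)","year":2019,"language":"eng","country":"China","publication_types":["Journal Article"],"headings":[{"descriptor_name":"Hypertension","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Telemedicine","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Diagnosis","descriptor_ui":null,"major":true,"qualifiers":[]}]}
{"pmid":"90000002","title":"Machine learning for diabetic nephropathy screening (synthetic)","year":2020,"language":"eng","country":"China","publication_types":["Journal Article"],"headings":[{"descriptor_name":"Diabetic Nephropathies","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Machine Learning","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Investigative Techniques","descriptor_ui":null,"major":true,"qualifiers":[]}]}
{"pmid":"90000003","title":"Pregnancy-induced hypertension registry informatics (synthetic)","year":2018,"language":"eng","country":"United States","publication_types":["Journal Article"],"headings":[{"descriptor_name":"Hypertension, Pregnancy-Induced","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Electronic Health Records","descriptor_ui":null,"major":true,"qualifiers":[]}]}
{"pmid":"90000004","title":"Myocardial ischemia outcomes with telemonitoring (synthetic)","year":2016,"language":"eng","country":"China","publication_types":["Journal Article"],"headings":[{"descriptor_name":"Myocardial Infarction","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Telemedicine","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Equipment and Supplies","descriptor_ui":null,"major":true,"qualifiers":[]}]}
{"pmid":"90000005","title":"A review of telecardiology (synthetic)","year":2019,"language":"eng","country":"United States","publication_types":["Journal Article","Review"],"headings":[{"descriptor_name":"Heart Diseases","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Telemedicine","descriptor_ui":null,"major":true,"qualifiers":[]}]}
{"pmid":"90000006","title":"A bibliometric overview of health informatics (synthetic)","year":2018,"language":"eng","country":"China","publication_types":["Journal Article"],"headings":[{"descriptor_name":"Public Health","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Medical Informatics","descriptor_ui":null,"major":true,"qualifiers":[]}]}
{"pmid":"90000007","title":"Evidence synthesis methods in informatics (synthetic)","year":2019,"language":"eng","country":"United States","publication_types":["Journal Article"],"headings":[{"descriptor_name":"Meta-Analysis as Topic","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Public Health","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Telemedicine","descriptor_ui":null,"major":true,"qualifiers":[]}]}
{"pmid":"90000008","title":"Epidemiology of infections (synthetic, no informatics topic)","year":2014,"language":"eng","country":"China","publication_types":["Journal Article"],"headings":[{"descriptor_name":"Infections","descriptor_ui":null,"major":true,"qualifiers":[]},{"descriptor_name":"Epidemiology","descriptor_ui":null,"major":true,"qualifiers":[]}]}
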
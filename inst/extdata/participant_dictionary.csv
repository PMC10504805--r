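column,type,allowed_values,description
id,string,any,opaque participant identifier
dentate_2006,boolean,TRUE|FALSE,baseline (2006) answer: has NOT lost all natural permanent teeth
edentulous_2018,boolean,TRUE|FALSE,follow-up (2018) answer: has lost all natural permanent teeth
age,integer,>= 0,age in whole years at baseline
race,category,Caucasian|AfricanAmerican|Hispanic|Other,race/ethnicity
gender,category,Female|Male,gender
education,category,NoHS|LessThanCollege|CollegePlus,highest education/degree
smoking,category,Current|Former|Never,smoking status
dental_visit_2y,category,Within2y|Over2y,last dental visit within 2 years or longer ago
alcohol,category,Drinks|DoesNotDrink,ever drinks alcoholic beverages
cognition_score,integer,0-35,summary cognition score (dichotomized at 23 in models)
self_rated_health,category,GoodPlus|FairPoor,self-rated general health
lonely,category,Yes|No,felt lonely much of the past week
income,category,Lt25k|From25to75k|Ge75k,annual household income category (USD)
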
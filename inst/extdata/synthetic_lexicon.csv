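surface,canonical,vocab,concept_id,behavior_category
autism spectrum disorder,autism spectrum disorder,HPO,HP:SYN0001,
autism,autism,HPO,HP:SYN0002,
abnormal aggressive impulsive or violent behavior,abnormal aggressive impulsive or violent behavior,HPO,HP:SYN0003,
intellectual disability,intellectual disability,HPO,HP:SYN0004,
spitting,Spitting,UMLS,CUI:SYN0001,
tantrum,Temper tantrum,UMLS,CUI:SYN0002,
anxiety,Anxiety,UMLS,CUI:SYN0003,
autism,Autism,UMLS,CUI:SYN0004,
community,community,ERIC,,
special education,special education,ERIC,,
early intervention,early intervention,ERIC,,
individualized education program,individualized education program,ERIC,,
respite care,respite care,AIRS,,
financial assistance,financial assistance,AIRS,,
support groups,support group,AIRS,,
child,child,AGE,,
children,child,AGE,,
toddler,child,AGE,,
teen,teen,AGE,,
teenager,teen,AGE,,
adolescent,teen,AGE,,
adult,adult,AGE,,
adults,adult,AGE,,
insomnia,insomnia,BEHAVIOR,,sleep issues
night waking,night waking,BEHAVIOR,,sleep issues
sleep problems,sleep problems,BEHAVIOR,,sleep issues
sensory overload,sensory overload,BEHAVIOR,,sensory issues
sensory issues,sensory issues,BEHAVIOR,,sensory issues
hyperactivity,hyperactivity,BEHAVIOR,,hyperactivity
hyperactive,hyperactive,BEHAVIOR,,hyperactivity
inattention,inattention,BEHAVIOR,,inattention
distractibility,distractibility,BEHAVIOR,,inattention
repetitive behavior,repetitive behavior,BEHAVIOR,,repetitive behavior
hand flapping,hand flapping,BEHAVIOR,,repetitive behavior
speech delay,speech delay,BEHAVIOR,,speech and language development
language development,language development,BEHAVIOR,,speech and language development
adaptive behavior,adaptive behavior,BEHAVIOR,,adaptive behavior
daily living skills,daily living skills,BEHAVIOR,,adaptive behavior
cognitive development,cognitive development,BEHAVIOR,,cognitive development
learning delay,learning delay,BEHAVIOR,,cognitive development
social skills,social skills,BEHAVIOR,,social skills
making friends,making friends,BEHAVIOR,,social skills
aggressive behavior,aggressive behavior,BEHAVIOR,,behavioral concerns
hitting,hitting,BEHAVIOR,,behavioral concerns
kicking,kicking,BEHAVIOR,,behavioral concerns
temper tantrums,temper tantrums,BEHAVIOR,,behavioral concerns
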
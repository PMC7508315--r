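# Synthetic health-tip pool: 54 one-way messages in 11 topical subsets.
# All content is invented fixture text for testing and simulation.

[hydration]
Tip: drink water all day long - staying hydrated helps keep pain crises away.
Tip: carry a water bottle to school and refill it at lunch.
Tip: if your urine is dark, you need more water. Aim for pale yellow.
Tip: warm drinks count too - soup and tea help you stay hydrated in winter.
Tip: drink extra water before sports or time outside in the heat.

[pain-management]
Tip: tell an adult early when pain starts - early treatment works best.
Tip: a heating pad on the sore spot can ease mild pain. Never use ice.
Tip: rest and slow breathing can help while your medicine starts working.
Tip: keep your pain medicine where you can find it fast.
Tip: rate your pain 1-10 so your care team knows how you feel.

[medication]
Tip: take your daily medicine at the same time every day.
Tip: set a phone alarm so you never miss a dose.
Tip: refill prescriptions a week before they run out.
Tip: never share your medicine or take someone else's.
Tip: bring your medicine list to every clinic visit.

[temperature]
Tip: dress in layers - getting too cold can trigger a crisis.
Tip: avoid swimming in cold water; warm pools are safer.
Tip: in summer, stay in the shade and take breaks from the heat.
Tip: a fever over 101 F is an emergency - get checked right away.
Tip: keep a blanket handy on long car or bus rides with air conditioning.

[rest]
Tip: aim for 8-10 hours of sleep - your body repairs itself at night.
Tip: short rest breaks during busy days help prevent exhaustion.
Tip: keep screens off for the last half hour before bed.
Tip: a regular bedtime keeps your energy steadier all week.
Tip: listen to your body - resting when tired is smart, not lazy.

[school]
Tip: tell a teacher or the school nurse about your sickle cell plan.
Tip: keep a water bottle and hall pass handy at school.
Tip: ask for notes or extra time when you miss class for clinic visits.
Tip: a 504 plan can make school easier - ask your care team about it.
Tip: pack your morning medicine the night before a school day.

[exercise]
Tip: light exercise is good - stop and rest when you feel winded.
Tip: warm up slowly before any sport and cool down after.
Tip: drink water before, during and after activity.
Tip: choose activities you can pause anytime, like walking or biking.
Tip: tell your coach you may need extra water and rest breaks.

[nutrition]
Tip: colorful fruits and veggies help your body make healthy blood cells.
Tip: foods with folate - beans, greens, oranges - are extra good for you.
Tip: eat regular meals; skipping meals can leave you drained.
Tip: a healthy snack after school keeps your energy up for homework.
Tip: limit energy drinks - they can dehydrate you.

[emotions]
Tip: it is okay to feel frustrated about sickle cell - talking helps.
Tip: share how you feel with someone you trust today.
Tip: deep slow breaths can calm both stress and pain.
Tip: keeping a journal can help you spot what triggers rough days.
Tip: you are more than your illness - make time for things you love.

[clinic-visits]
Tip: write down questions before your next clinic visit.
Tip: never skip a checkup even when you feel great.
Tip: know your baseline labs - ask your care team to explain them.
Tip: arrive a few minutes early so labs do not delay your visit.
Tip: ask for a visit summary so you remember the plan.

[transition]
Tip: learn the names and doses of your own medicines - it is your health.
Tip: practice calling the clinic yourself to book a visit.
Tip: by 18 you will see adult doctors - start learning your health story now.
Tip: keep your own copy of your health records and emergency plan.
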
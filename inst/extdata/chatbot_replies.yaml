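# Reply templates for the conversational search assistant.
# Edit tone here; the dialog logic does not change.
greet: "Hi! I can help you find a step or action that fits how you're doing. How are you feeling right now?"
elicit_mood: "How are you feeling right now?"
reprompt_mood: "No rush — even a word or two about how you're feeling helps."
elicit_topic: "Thanks. What would you like some help with, or what's on your mind?"
reprompt_topic: "Anything at all — a topic, a situation, or a goal works."
confirm: "Got it. I'll look for something that might help. Ready? (say anything to continue)"
done: "Here's what I found for you. A moderator will also see a short profile of this chat."
skipped: "That's okay, we can move on."
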